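#' Configuration of the synthetic panoramic-radiograph generator
#'
#' The generator emulates the properties of panoramic dental radiographs
#' that the pipeline depends on, without claiming anatomical realism: a
#' bright arch-shaped teeth band inside a larger noisy background with a
#' variable field of view; 32 tooth-like shapes in the FDI layout (upper
#' row quadrants 1-2, lower row quadrants 3-4, the patient's right on the
#' image's left); focal dark wedge lesions at the tooth necks; spatially
#' correlated per-tooth disease labels with stronger coupling between
#' horizontally adjacent teeth and damped coupling at the third molars; and
#' several imperfect annotators with partially overlapping masks and noisy
#' tooth labels.
#'
#' Per-tooth lesion base rates default to a gradient over tooth types
#' (incisor 0.30, canine 0.28, premolar 0.22, molar 0.18, third molar
#' 0.12), mirroring the clinical observation that anterior teeth co-occur
#' strongly and third molars stand apart. Label correlation follows a
#' one-dimensional autologistic chain along each jaw's arch:
#' `logit P(y_k = 1 | y_(k-1)) = qlogis(base_k) + coupling * damp * y_(k-1)`
#' with `damp = end_damping` when the link touches a third molar. Coupling
#' 0 gives exactly independent labels.
#'
#' @param image_shape `(height, width)`, default `c(128, 256)`; desk-scale
#'   tests use `c(64, 128)`. Must be at least `c(48, 96)`.
#' @param n_annotators Number of simulated annotators (default 5).
#' @param lesion_prevalence Length-32 vector of per-tooth base rates in the
#'   fixed FDI slot order, or `NULL` for the default gradient.
#' @param adjacency_coupling Nonnegative chain coupling in logit units
#'   (default 1.5).
#' @param end_damping Multiplier on the coupling for links touching a
#'   position-8 tooth (default 0.3).
#' @param annotator_noise List: `flip_rate` (per-tooth label flip
#'   probability, scalar or per annotator, must be `< 0.5`), `morph_prob`
#'   (probability an annotator's mask is dilated or eroded by one pixel),
#'   `omission_rate` (probability a lesion component is dropped),
#'   `addition_rate` (probability of one spurious blob).
#' @param background_variability List: `margin_frac` (maximum field-of-view
#'   margin as a fraction of each dimension) and `noise_sd` (intensity
#'   noise standard deviation).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(image_shape = c(128L, 256L), n_annotators = 5L,
                             lesion_prevalence = NULL,
                             adjacency_coupling = 1.5, end_damping = 0.3,
                             annotator_noise = list(flip_rate = 0.1,
                                                    morph_prob = 0.5,
                                                    omission_rate = 0.15,
                                                    addition_rate = 0.1),
                             background_variability = list(margin_frac = 0.12,
                                                           noise_sd = 0.04)) {
  image_shape <- as.integer(image_shape)
  if (image_shape[1] < 48L || image_shape[2] < 96L)
    stop("image too small to place 32 teeth: need at least 48 x 96")
  if (is.null(lesion_prevalence)) {
    ch <- fdi_chart()
    base <- c(incisor = 0.30, canine = 0.28, premolar = 0.22,
              molar = 0.18)[ch$type]
    base[ch$position == 8L] <- 0.12
    lesion_prevalence <- unname(base)
  }
  if (length(lesion_prevalence) == 1L)
    lesion_prevalence <- rep(lesion_prevalence, 32L)
  stopifnot(length(lesion_prevalence) == 32L,
            all(lesion_prevalence >= 0 & lesion_prevalence <= 1),
            adjacency_coupling >= 0)
  fr <- annotator_noise$flip_rate
  if (any(fr >= 0.5))
    stop("annotator flip rate must be < 0.5 (majority vote guarantee)")
  structure(list(image_shape = image_shape,
                 n_annotators = as.integer(n_annotators),
                 lesion_prevalence = lesion_prevalence,
                 adjacency_coupling = adjacency_coupling,
                 end_damping = end_damping,
                 annotator_noise = annotator_noise,
                 background_variability = background_variability),
            class = "synthetic_config")
}

# arch layout: 16 positions per jaw, left-to-right on the image.
# position k (1..16) -> zero-based FDI slot
arch_slot <- function(k, jaw) {
  if (jaw == "upper") ifelse(k <= 8L, 8L - k, k - 1L)
  else ifelse(k <= 8L, 32L - k, k + 7L)
}

case_geometry <- function(config) {
  h <- config$image_shape[1]; w <- config$image_shape[2]
  mf <- config$background_variability$margin_frac
  m <- stats::runif(4, 0.02, max(mf, 0.021))   # top, bottom, left, right
  xl <- (m[3] + 0.05) * w
  xr <- (1 - m[4] - 0.05) * w
  cx <- (xl + xr) / 2
  th <- 0.16 * h
  tw <- (xr - xl) / 16
  occl <- function(x) 0.5 * h + 0.06 * h * ((x - cx) / ((xr - xl) / 2))^2
  xs <- xl + tw * (seq_len(16) - 0.5)
  centers <- matrix(NA_real_, 32L, 2L)
  for (k in seq_len(16)) {
    oc <- occl(xs[k])
    centers[arch_slot(k, "upper") + 1L, ] <- c(oc - 0.62 * th, xs[k])
    centers[arch_slot(k, "lower") + 1L, ] <- c(oc + 0.62 * th, xs[k])
  }
  list(margins = m, xl = xl, xr = xr, occl = occl, th = th, tw = tw,
       xs = xs, centers = centers)
}

sample_chain_labels <- function(config) {
  y <- integer(32L)
  for (jaw in c("upper", "lower")) {
    prev <- 0L
    for (k in seq_len(16)) {
      slot <- arch_slot(k, jaw)
      pos <- slot %% 8L + 1L
      base <- config$lesion_prevalence[slot + 1L]
      damp <- if (pos == 8L ||
                  (k > 1L && (arch_slot(k - 1L, jaw) %% 8L + 1L) == 8L))
        config$end_damping else 1
      eta <- stats::qlogis(pmin(pmax(base, 1e-6), 1 - 1e-6)) +
        config$adjacency_coupling * damp * prev
      yk <- stats::rbinom(1L, 1L, stats::plogis(eta))
      if (base == 0) yk <- 0L
      if (base == 1) yk <- 1L
      y[slot + 1L] <- yk
      prev <- yk
    }
  }
  y
}

#' Sample tooth-label vectors from the autologistic arch chain
#'
#' Draws `n` length-32 label vectors from the generator's label model alone
#' (no image rendering), for studying the induced co-occurrence structure
#' at large `n`.
#'
#' @param config A [synthetic_config()].
#' @param n Number of vectors.
#' @param seed Optional integer seed.
#' @return `n x 32` binary matrix.
#' @export
sample_tooth_labels <- function(config = synthetic_config(), n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t(vapply(seq_len(n), function(i) sample_chain_labels(config), integer(32L)))
}

#' Generate one synthetic panoramic case
#'
#' Renders the radiograph, its teeth-region mask and polygon (vertices in
#' the conventional right-TMJ, right-mandible, left-mandible, left-TMJ
#' annotation order), samples correlated tooth labels from the autologistic
#' chain, draws a dark wedge lesion at the neck of every diseased tooth,
#' and simulates the annotators. Deterministic given `seed`.
#'
#' @param config A [synthetic_config()].
#' @param seed Optional integer seed (uses the current RNG state when
#'   `NULL`).
#' @return A `synthetic_case`: `image`, `roi_mask`, `roi_polygon` (vertex
#'   matrix, columns row/col), `true_tooth_labels`, `true_lesion_mask`,
#'   `annotator_masks` (list), `annotator_labels` (`L x 32` matrix),
#'   `tooth_centers` (`32 x 2` matrix of row/col).
#' @export
generate_case <- function(config = synthetic_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  h <- config$image_shape[1]; w <- config$image_shape[2]
  geo <- case_geometry(config)
  rows <- matrix(rep(seq_len(h), times = w), h, w)
  cols <- matrix(rep(seq_len(w), each = h), h, w)

  # field of view: dark frame around the exposed area
  exposed <- rows > geo$margins[1] * h & rows < (1 - geo$margins[2]) * h &
    cols > geo$margins[3] * w & cols < (1 - geo$margins[4]) * w

  # teeth band (the ROI): between the two arch-following curves
  occl_c <- geo$occl(cols)
  band <- cols >= geo$xl & cols <= geo$xr &
    rows >= occl_c - 1.55 * geo$th & rows <= occl_c + 1.55 * geo$th
  roi_mask <- (band & exposed) + 0L

  img <- matrix(0.03, h, w)
  img[exposed] <- 0.14
  img[band & exposed] <- 0.40

  # tooth-like bright ellipses
  centers <- geo$centers
  for (t in seq_len(32L)) {
    cr <- centers[t, 1]; cc <- centers[t, 2]
    ell <- ((rows - cr) / (0.55 * geo$th))^2 +
      ((cols - cc) / (0.38 * geo$tw))^2 <= 1
    img[ell & exposed] <- 0.85 + stats::runif(1, -0.05, 0.05)
  }

  y <- sample_chain_labels(config)
  lesion <- matrix(FALSE, h, w)
  for (t in which(y == 1L)) {
    cr <- centers[t, 1]; cc <- centers[t, 2]
    dir <- if (t <= 16L) -1 else 1            # away from the occlusal line
    sev <- stats::runif(1, 0.7, 1.1)
    wh <- 0.75 * geo$th * sev                 # wedge height
    ww <- 0.48 * geo$tw * sev                 # wedge half-width at the neck
    d <- dir * (rows - (cr + dir * 0.30 * geo$th))
    wedge <- d >= 0 & d <= wh & abs(cols - cc) <= ww * (1 - d / wh)
    lesion <- lesion | (wedge & exposed)
  }
  img[lesion] <- 0.08
  img <- img + matrix(stats::rnorm(h * w, 0,
                                   config$background_variability$noise_sd),
                      h, w)
  img <- pmin(pmax(img, 0), 1)

  # ROI polygon in annotation order: right TMJ (image-left band end), along
  # the mandibular (lower) edge right to left of the patient, left TMJ,
  # then back along the maxillary (upper) edge
  px <- seq(geo$xl, geo$xr, length.out = 24)
  lower_edge <- cbind(geo$occl(px) + 1.55 * geo$th, px)
  upper_edge <- cbind(geo$occl(rev(px)) - 1.55 * geo$th, rev(px))
  roi_polygon <- rbind(upper_edge[nrow(upper_edge), ],   # right TMJ corner
                       lower_edge, upper_edge)

  case <- structure(list(image = img, roi_mask = roi_mask,
                         roi_polygon = roi_polygon,
                         true_tooth_labels = y,
                         true_lesion_mask = lesion + 0L,
                         tooth_centers = centers,
                         config = config),
                    class = "synthetic_case")
  ann <- simulate_annotators(case, config)
  case$annotator_masks <- ann$annotator_masks
  case$annotator_labels <- ann$annotator_labels
  case
}

#' Simulate imperfect annotators for one case
#'
#' Each annotator's tooth labels are the truth flipped independently per
#' tooth at that annotator's flip rate. Each annotator's lesion mask is a
#' morphologically perturbed copy of the true mask (one-pixel dilation or
#' erosion with probability `morph_prob`), with whole lesion components
#' dropped at `omission_rate` and, at `addition_rate`, one small spurious
#' blob inside the teeth band. With all noise parameters 0 every annotator
#' reproduces the truth exactly. For flip rates below 0.5, majority voting
#' across annotators recovers the true labels more accurately than any
#' single annotator.
#'
#' @param case A `synthetic_case` (only its truth fields are used).
#' @param config A [synthetic_config()].
#' @param seed Optional integer seed.
#' @return List with `annotator_masks` (list of binary matrices) and
#'   `annotator_labels` (`L x 32` matrix, rows named `a1..aL`).
#' @export
simulate_annotators <- function(case, config = case$config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- config$n_annotators
  nz <- config$annotator_noise
  fr <- rep(nz$flip_rate, length.out = L)
  if (any(fr >= 0.5)) stop("annotator flip rate must be < 0.5")
  truth_y <- case$true_tooth_labels
  truth_m <- case$true_lesion_mask
  labels <- matrix(0L, L, 32L, dimnames = list(paste0("a", seq_len(L)),
                                               fdi_chart()$code))
  masks <- vector("list", L)
  for (l in seq_len(L)) {
    flips <- stats::rbinom(32L, 1L, fr[l])
    labels[l, ] <- as.integer(xor(truth_y == 1L, flips == 1L))
    m <- truth_m > 0
    if (nz$morph_prob > 0 && stats::runif(1) < nz$morph_prob && any(m)) {
      kern <- EBImage::makeBrush(3L, "box")
      m <- if (stats::runif(1) < 0.5) EBImage::dilate(m + 0, kern) > 0
      else EBImage::erode(m + 0, kern) > 0
    }
    if (nz$omission_rate > 0 && any(m)) {
      comp <- EBImage::bwlabel(m + 0)
      for (id in seq_len(max(comp))) {
        if (stats::runif(1) < nz$omission_rate) m[comp == id] <- FALSE
      }
    }
    if (nz$addition_rate > 0 && stats::runif(1) < nz$addition_rate) {
      fg <- which(case$roi_mask > 0, arr.ind = TRUE)
      if (nrow(fg) > 0) {
        ctr <- fg[sample.int(nrow(fg), 1L), ]
        rr <- matrix(rep(seq_len(nrow(m)), times = ncol(m)), nrow(m))
        cc <- matrix(rep(seq_len(ncol(m)), each = nrow(m)), nrow(m))
        m <- m | ((rr - ctr[1])^2 + (cc - ctr[2])^2 <= 2^2)
      }
    }
    masks[[l]] <- m + 0L
  }
  list(annotator_masks = masks, annotator_labels = labels)
}

#' @export
print.synthetic_case <- function(x, ...) {
  cat("Synthetic panoramic case", paste(dim(x$image), collapse = "x"),
      "|", sum(x$true_tooth_labels), "diseased teeth |",
      sum(x$true_lesion_mask), "lesion pixels |",
      length(x$annotator_masks), "annotators\n")
  invisible(x)
}

#' Generate and reload an on-disk synthetic dataset
#'
#' `generate_dataset()` writes `n` cases to `out_dir` in the interchange
#' formats the rest of the pipeline reads: grayscale PNGs for images
#' (`{id}.png`), teeth-region masks (`{id}_roi.png`), true lesion masks
#' (`{id}_lesion.png`), per-annotator lesion masks (`{id}_{annotator}.png`),
#' one long-format label CSV (`labels.csv`, including a `truth` annotator
#' row), and `manifest.json` recording the generating configuration, seed,
#' a 70/15/15 train/validation/test split and the MD5 of every file. Two
#' runs with the same seed produce byte-identical files.
#'
#' @param n Number of cases.
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @param out_dir Output directory (created if missing).
#' @return The manifest, invisibly.
#' @export
generate_dataset <- function(n, config = synthetic_config(), seed = 1L,
                             out_dir) {
  stopifnot(n >= 1L)
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("output directory is not writable")
  set.seed(seed)
  ids <- sprintf("case%04d", seq_len(n))
  votes_by_image <- list()
  files <- character(0)
  for (i in seq_len(n)) {
    case <- generate_case(config)
    id <- ids[i]
    f <- c(file.path(out_dir, paste0(id, ".png")),
           file.path(out_dir, paste0(id, "_roi.png")),
           file.path(out_dir, paste0(id, "_lesion.png")))
    write_gray_png(case$image, f[1])
    write_gray_png(case$roi_mask, f[2])
    write_gray_png(case$true_lesion_mask, f[3])
    for (l in seq_along(case$annotator_masks)) {
      fa <- file.path(out_dir, paste0(id, "_a", l, ".png"))
      write_gray_png(case$annotator_masks[[l]], fa)
      f <- c(f, fa)
    }
    votes <- rbind(case$annotator_labels,
                   truth = case$true_tooth_labels)
    votes_by_image[[id]] <- votes
    files <- c(files, f)
  }
  label_path <- file.path(out_dir, "labels.csv")
  write_tooth_labels(votes_by_image, label_path)
  files <- c(files, label_path)
  n_tr <- max(1L, floor(0.7 * n))
  n_val <- min(n - n_tr, ceiling(0.15 * n))
  split <- list(train = ids[seq_len(n_tr)],
                validation = ids[n_tr + seq_len(n_val)],
                test = if (n_tr + n_val < n) ids[(n_tr + n_val + 1L):n]
                       else character(0))
  manifest <- list(n = n, seed = seed, config = unclass(config),
                   split = split,
                   files = tibble::tibble(file = basename(files),
                                          md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = I(10), auto_unbox = TRUE)
  invisible(manifest)
}

#' @rdname generate_dataset
#' @param dir Directory written by `generate_dataset()`.
#' @return `load_synthetic_dataset()`: list with `manifest` and `cases`
#'   (per case: `id`, `image`, `roi_mask`, `lesion_mask`,
#'   `annotator_masks`, `votes` the `L x 32` annotator matrix and `truth`).
#' @export
load_synthetic_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  labels <- read_tooth_labels(file.path(dir, "labels.csv"))
  ids <- sprintf("case%04d", seq_len(manifest$n))
  L <- manifest$config$n_annotators
  cases <- lapply(ids, function(id) {
    votes_all <- tooth_label_matrix(labels, id)
    ann_rows <- setdiff(rownames(votes_all), "truth")
    list(id = id,
         image = read_gray_png(file.path(dir, paste0(id, ".png"))),
         roi_mask = (read_gray_png(file.path(dir, paste0(id, "_roi.png"))) >
                       0.5) + 0L,
         lesion_mask = (read_gray_png(file.path(dir,
                                                paste0(id, "_lesion.png"))) >
                          0.5) + 0L,
         annotator_masks = lapply(seq_len(L), function(l)
           (read_gray_png(file.path(dir, paste0(id, "_a", l, ".png"))) >
              0.5) + 0L),
         votes = votes_all[ann_rows, , drop = FALSE],
         truth = as.integer(votes_all["truth", ]))
  })
  list(manifest = manifest, cases = cases)
}
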