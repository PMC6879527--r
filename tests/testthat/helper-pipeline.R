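# Shared desk-scale study pipeline for the end-to-end tests. Everything is
# computed once per test run and cached; all sizes refer to 64 x 128
# synthetic radiographs.

desk_env <- new.env(parent = emptyenv())

desk_config <- function() synthetic_config(image_shape = c(64, 128))

prep_desk_case <- function(case, out_shape = c(64L, 128L)) {
  pm <- postprocess_mask(case$roi_mask)
  crop <- extract_roi(case$image, pm, out_shape = out_shape)
  union <- aggregate_lesion_mask(case$annotator_masks, 1)
  list(crop = crop,
       union_lesion = roi_warp_mask(union, crop),
       truth_lesion = roi_warp_mask(case$true_lesion_mask, crop),
       labels = aggregate_tooth_labels(case$annotator_labels, 3),
       truth = case$true_tooth_labels,
       case = case)
}

desk_cases <- function() {
  if (is.null(desk_env$prep)) {
    cfg <- desk_config()
    set.seed(2026)
    cases <- lapply(seq_len(150), function(i) generate_case(cfg))
    desk_env$prep <- lapply(cases, prep_desk_case)
  }
  desk_env$prep
}

desk_seg_config <- function(epochs)
  segmenter_config(c(64, 128), depth = 3, base_channels = 8,
                   epochs = epochs, learning_rate = 1e-3)

# ROI segmentation study: 40 training / 8 validation pairs per seed
desk_roi_run <- function(seed, epochs = 8) {
  prep <- desk_cases()
  pairs <- lapply(prep[1:48], function(p)
    list(image = p$case$image, mask = p$case$roi_mask))
  cfg <- segmenter_config(c(64, 128), depth = 2, base_channels = 8,
                          epochs = epochs, learning_rate = 1e-3)
  m <- train_roi_segmenter(pairs[1:40], cfg, seed = seed,
                           validation = pairs[41:48])
  list(model = m, val_dice = utils::tail(m$history$val_dice, 1))
}

# lesion pre-training study: 40 crops, held-out dice on 8 vs the true masks
desk_lesion_run <- function(seed, epochs = 6) {
  prep <- desk_cases()
  tr <- lapply(prep[1:40], function(p)
    list(image = p$crop$image, mask = p$union_lesion))
  out <- train_lesion_segmenter(tr, desk_seg_config(epochs), gamma = 2,
                                seed = seed)
  dices <- vapply(prep[41:48], function(p)
    dice(predict_mask(out$model, p$crop$image) >= 0.5, p$truth_lesion),
    numeric(1))
  list(model = out$model, encoder = out$encoder, val_dice = mean(dices))
}

desk_lesion <- function() {
  if (is.null(desk_env$lesion)) desk_env$lesion <- desk_lesion_run(1)
  desk_env$lesion
}

desk_clf_config <- function(epochs = 16)
  classifier_config(c(64, 128), depth = 3, base_channels = 8,
                    epochs = epochs, learning_rate = 1e-3)

# photometric-only augmentation: geometric jitter above the tooth pitch
# breaks the tooth-slot correspondence at this resolution
desk_clf_augment <- function() augment_params(0, 0, 0.15)

desk_classifier <- function() {
  if (is.null(desk_env$clf)) {
    prep <- desk_cases()
    tr <- prep[1:100]
    cooc <- build_cooccurrence(do.call(rbind, lapply(tr, `[[`, "labels")))
    dataset <- lapply(tr, function(p) list(image = p$crop, labels = p$labels))
    clf <- train_tooth_classifiers(dataset, desk_lesion()$encoder, cooc,
                                   desk_clf_config(), seed = 1,
                                   augmentation = desk_clf_augment())
    te <- prep[121:150]
    scores <- t(vapply(te, function(p) predict(clf, p$crop), numeric(32)))
    labels <- do.call(rbind, lapply(te, `[[`, "truth"))
    val <- prep[101:110]
    val_scores <- t(vapply(val, function(p) predict(clf, p$crop), numeric(32)))
    val_labels <- do.call(rbind, lapply(val, `[[`, "truth"))
    desk_env$clf <- list(clf = clf, scores = scores, labels = labels,
                         val_scores = val_scores, val_labels = val_labels)
  }
  desk_env$clf
}
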