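# End-to-end experiment driver: images -> segmentation -> crops ->
# descriptors -> weight-stratified split -> fusion -> grid-searched
# classifier -> macro-averaged report.

.descriptor_funs <- function() {
  list(sdpsf = function(crop) compute_sdpsf(crop$contour),
       hog = compute_hog,
       hu = compute_hu,
       lbp = compute_eqlbp,
       glcm = compute_glcm,
       color = compute_color_hist)
}

#' Segment, crop and extract descriptors for a set of pupa images
#'
#' @param images named list of `pupa_image` objects (names are image ids,
#'   e.g. `<pupa_id>_<posture>`), as returned in `generate_dataset()$images`.
#' @param descriptors subset of c("sdpsf", "hog", "hu", "lbp", "glcm",
#'   "color"), or "deep" handled through `backbone`.
#' @param backbone optional `backbone_spec`; when given, a "deep" block of
#'   1000-dim CNN features is added.
#' @param area_threshold_frac passed to [segment_pupa()].
#' @return list(features = named list of matrices (rows = image ids),
#'   crops = list of `crop_result`).
#' @export
extract_features_batch <- function(images,
                                   descriptors = c("sdpsf", "color"),
                                   backbone = NULL,
                                   area_threshold_frac = 0.02) {
  funs <- .descriptor_funs()
  bad <- setdiff(descriptors, names(funs))
  if (length(bad)) stop("unknown descriptor(s): ", paste(bad, collapse = ", "))
  ids <- names(images)
  rows <- lapply(ids, function(id) {
    img <- images[[id]]
    contour <- segment_pupa(img$pixels, area_threshold_frac)
    crop <- crop_centered(img$pixels, contour)
    feats <- lapply(descriptors, function(d) funs[[d]](crop))
    names(feats) <- descriptors
    if (!is.null(backbone)) feats$deep <- extract_features(backbone, crop)
    feats
  })
  names(rows) <- ids
  all_desc <- c(descriptors, if (!is.null(backbone)) "deep")
  features <- lapply(all_desc, function(d) {
    m <- do.call(rbind, lapply(rows, `[[`, d))
    rownames(m) <- ids
    m
  })
  names(features) <- all_desc
  list(features = features)
}

#' Run a complete identification experiment on a synthetic dataset
#'
#' Generates (or accepts) a rendered dataset, splits it by weight, extracts
#' and fuses the requested descriptors (reducer fit on the training rows
#' only), grid-searches the classifier with 5-fold CV on the training split,
#' and evaluates on the held-out test split with macro metrics and
#' one-vs-rest PR/ROC curves. The three tasks reuse the same features and
#' differ only in labeling.
#'
#' @param dataset a rendered `pupa_dataset` (images present).
#' @param task "species" (5-class), "sex" (2-class) or "species_sex"
#'   (10-class).
#' @param descriptors descriptor names for [extract_features_batch()].
#' @param classifier a [classifier_spec()].
#' @param ratios split ratios, c(8, 2) or c(8, 1, 1).
#' @param target_dim fusion compression target (default 500).
#' @param seed experiment seed (splitting tie-breaks).
#' @return list(report = `eval_report`, curves, model = `pupa_model`,
#'   split = manifest with split column, fusion = `fusion_fit`,
#'   predictions = data.frame).
#' @export
run_experiment <- function(dataset, task = c("species_sex", "species", "sex"),
                           descriptors = c("sdpsf", "color"),
                           classifier = classifier_spec("svm"),
                           ratios = c(8, 2), target_dim = 500, seed = 1) {
  task <- match.arg(task)
  stopifnot(inherits(dataset, "pupa_dataset"))
  if (!length(dataset$images))
    stop("dataset must be rendered (generate_dataset(..., render = TRUE))")
  man <- split_dataset(dataset$manifest, ratios, seed)
  man$image_id <- sprintf("%s_%s", man$pupa_id, man$posture)
  man$label <- switch(task, species = man$species, sex = man$sex,
                      species_sex = man$class)
  ex <- extract_features_batch(dataset$images, descriptors)
  tr_ids <- man$image_id[man$split == "train"]
  te_ids <- man$image_id[man$split == "test"]
  fusion <- fit_fusion(lapply(ex$features, function(m) m[tr_ids, , drop = FALSE]),
                       target_dim = target_dim)
  Xtr <- apply_fusion(fusion, lapply(ex$features, function(m) m[tr_ids, , drop = FALSE]))
  Xte <- apply_fusion(fusion, lapply(ex$features, function(m) m[te_ids, , drop = FALSE]))
  ytr <- man$label[match(tr_ids, man$image_id)]
  yte <- man$label[match(te_ids, man$image_id)]
  model <- grid_search_train(Xtr, ytr, classifier)
  pred <- predict(model, Xte)
  report <- compute_metrics(yte, pred$class, levels = model$levels)
  curves <- pr_roc_curves(yte, pred$scores)
  list(report = report, curves = curves, model = model, split = man,
       fusion = fusion,
       predictions = data.frame(image_id = te_ids, truth = yte,
                                predicted = as.character(pred$class),
                                stringsAsFactors = FALSE))
}
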