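#' End-to-end pipeline configuration
#'
#' Bundles all stage configurations. Length scales (median kernel, ROI
#' frame) are defined at the clinical 1944-px frame height and scaled
#' proportionally for smaller frames; the top-hat structuring radius is
#' defined in the normalized ROI frame and therefore not rescaled.
#'
#' @param image_height frame height in px of the images to be processed.
#' @param n_bins gray-level bin count for texture features.
#' @param roi_size normalized ROI frame, `c(height, width)`; default is
#'   the clinical 596 x 1104 scaled by `image_height / 1944`.
#' @param preproc,search,segment,scales stage configurations.
#' @return object of class `cfs_config`.
#' @export
cfs_config <- function(image_height = 1944, n_bins = 32,
                       roi_size = NULL, preproc = NULL,
                       search = pupil_search_spec(),
                       segment = segment_config(),
                       scales = scale_set()) {
  s <- image_height / 1944
  if (is.null(roi_size)) roi_size <- pmax(round(c(596, 1104) * s), 16)
  if (is.null(preproc)) {
    mk <- max(3, round(21 * s))
    if (mk %% 2 == 0) mk <- mk + 1
    preproc <- preproc_config(median_kernel = mk)
  }
  structure(list(image_height = image_height, roi_size = roi_size,
                 preproc = preproc, search = search, segment = segment,
                 scales = scales, n_bins = n_bins),
            class = "cfs_config")
}

#' Desk-scale pipeline configuration
#'
#' [cfs_config()] scales the clinical 596 x 1104 ROI frame proportionally
#' to the input frame, which at small simulation frames (a few hundred px)
#' subsamples the sector and pushes micropunctate dots below the resolvable
#' scale. This configuration enlarges the normalized ROI frame by a fixed
#' factor so the sector is sampled at or above its native resolution while
#' every other parameter keeps its default.
#'
#' @param image_height frame height in px.
#' @param roi_factor ROI frame enlargement over the proportional default.
#' @param ... passed to [cfs_config()].
#' @return a [cfs_config()].
#' @export
desk_config <- function(image_height, roi_factor = 1.4, ...) {
  cfs_config(image_height,
             roi_size = pmax(round(c(596, 1104) * image_height / 1944 *
                                     roi_factor), 16), ...)
}

#' Extract the full 974-feature signature of one image
#'
#' Runs preprocessing, ROI localization, stain segmentation and the three
#' feature blocks. The output is ordered texture (837), morphology (9),
#' topology (128); block sizes are asserted on every call.
#'
#' @param image RGB array, 0-255.
#' @param cfg a [cfs_config()]; defaults to one scaled to the image height.
#' @return list `(features, geometry, stains)`; `features` is the named
#'   974-vector.
#' @export
extract_features <- function(image, cfg = cfs_config(dim(image)[1])) {
  pp <- preprocess_image(image, cfg$preproc)
  geo <- locate_roi(pp$image, cfg$search)
  roi <- extract_roi(image, geo, cfg$roi_size)
  stains <- segment_stains(roi$rgb, roi$mask, cfg$segment)
  tex <- texture_block(roi$rgb[, , 2], roi$mask, cfg$n_bins)
  mor <- morph_block(stains)
  names(mor) <- sprintf("morphology-%d", 1:9)
  topo <- topo_block(stains, cfg$scales)
  feats <- c(tex, mor, topo)
  stopifnot(length(tex) == 837, length(mor) == 9, length(topo) == 128,
            identical(names(feats), cfs_feature_names()))
  list(features = feats, geometry = geo, stains = stains)
}

#' Read an image file as a 0-255 RGB array
#'
#' @param path PNG file path.
#' @return height x width x 3 array, 0-255.
#' @export
read_eye_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  a[, , 1:3, drop = FALSE] * 255
}

#' Extract the feature table of a cohort or image directory
#'
#' Accepts a [make_cohort()] object or a directory containing PNG images
#' (with an optional `manifest.csv` holding grades). Images failing any
#' stage are skipped with a warning and recorded in the `failures`
#' attribute; the run continues.
#'
#' @param input a `cfs_cohort` or a directory path.
#' @param cfg a [cfs_config()]; by default scaled to the first image.
#' @param out_csv optional path; when set, the table is written as CSV.
#' @param progress print a dot per image.
#' @return data frame: `image`, `grade` (NA when unknown), 974 feature
#'   columns.
#' @export
run_extract <- function(input, cfg = NULL, out_csv = NULL,
                        progress = FALSE) {
  if (inherits(input, "cfs_cohort")) {
    imgs <- lapply(input, `[[`, "image")
    ids <- sprintf("eye_%04d", seq_along(input))
    grades <- vapply(input, function(e) e$truth$oss_grade, numeric(1))
  } else {
    files <- sort(list.files(input, pattern = "\\.png$", full.names = TRUE))
    imgs <- files
    ids <- basename(files)
    grades <- rep(NA_real_, length(files))
    mf <- file.path(input, "manifest.csv")
    if (file.exists(mf)) {
      man <- utils::read.csv(mf)
      grades <- man$grade[match(ids, man$filename)]
    }
  }
  if (!length(imgs)) stop("no input images")
  rows <- vector("list", length(imgs))
  failures <- character(0)
  for (i in seq_along(imgs)) {
    img <- tryCatch(
      if (is.character(imgs[[i]])) read_eye_image(imgs[[i]]) else imgs[[i]],
      error = function(e) NULL)
    res <- if (is.null(img)) NULL else
      tryCatch(extract_features(img, cfg %||% cfs_config(dim(img)[1])),
               error = function(e) { warning("skipping ", ids[i], ": ",
                                             conditionMessage(e)); NULL })
    if (is.null(res)) { failures <- c(failures, ids[i]); next }
    rows[[i]] <- res$features
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  keep <- !vapply(rows, is.null, logical(1))
  out <- cbind(data.frame(image = ids[keep], grade = grades[keep],
                          stringsAsFactors = FALSE),
               as.data.frame(do.call(rbind, rows[keep]),
                             check.names = FALSE))
  attr(out, "failures") <- failures
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Train and evaluate the full model grid
#'
#' Splits the table 8:2 with stratification, runs the selection cascade on
#' the training split only, builds the four signatures, and evaluates the
#' six classifiers on each signature with 10-fold cross-validation on the
#' training split and a final fit on the held-out test split.
#'
#' @param features a [run_extract()] table (or any data frame with a
#'   `grade` column plus the 974 feature columns).
#' @param seed seed controlling split, folds and learners.
#' @param models classifier kinds to evaluate.
#' @param signatures signature subset names to evaluate.
#' @param folds CV folds.
#' @return list: `split`, `selection`, `grid` (one row per model x
#'   signature with CV and test metrics), `test_predictions`, `models`.
#' @export
run_train_eval <- function(features, seed = 1L,
                           models = c("svm", "dt", "bt", "nb", "knn", "rf"),
                           signatures = c("A10", "NT10", "T5", "NT5"),
                           folds = 10) {
  if (!"grade" %in% names(features) || anyNA(features$grade))
    stop("labelled features required")
  fn <- intersect(cfs_feature_names(), names(features))
  if (length(fn) != 974)
    stop("features table must contain the 974 canonical feature columns")
  x <- as.matrix(features[, fn])
  y <- features$grade
  sp <- split_cohort(y, 0.8, seed)
  nz <- normalize_features(x[sp$train, ])
  sel <- select_features(nz$x, y[sp$train], seed = seed)
  grid <- list(); preds <- list(); mods <- list()
  for (sg in signatures) {
    sig <- sel$subsets[[sg]]
    if (!length(sig)) next
    for (mk in models) {
      spec <- model_spec(mk, seed = seed)
      cv <- cross_validate(x[sp$train, ], y[sp$train], sig, spec,
                           folds = folds, seed = seed)
      fp <- fit_predict(x[sp$train, ], y[sp$train], x[sp$test, ], sig, spec)
      cm <- confusion_matrix(y[sp$test], fp$labels,
                             classes = sort(unique(y)))
      tm <- confusion_metrics(cm)
      auc <- roc_auc(fp$scores, y[sp$test])
      grid[[paste(mk, sg)]] <- data.frame(
        model = mk, signature = sg,
        cv_acc = cv$metrics$acc,
        acc = tm$acc, sen = tm$sen, pre = tm$pre, spe = tm$spe,
        f_measure = tm$f_measure, auc = unname(auc["auc_micro"]))
      preds[[paste(mk, sg)]] <- list(labels = fp$labels,
                                     scores = fp$scores,
                                     truth = y[sp$test], confusion = cm)
      mods[[paste(mk, sg)]] <- fp$model
    }
  }
  list(split = sp, selection = sel,
       grid = do.call(rbind, c(grid, list(make.row.names = FALSE))),
       test_predictions = preds, models = mods)
}

#' Grade a single image with a fitted model
#'
#' @param image RGB array, 0-255.
#' @param model a `cfs_classifier` from [fit_predict()]`$model`.
#' @param norm the frozen normalization statistics from the same fit.
#' @param signature the feature names the model was trained on.
#' @param cfg a [cfs_config()].
#' @return list `(grade, scores)`.
#' @export
grade_image <- function(image, model, norm, signature,
                        cfg = cfs_config(dim(image)[1])) {
  f <- extract_features(image, cfg)$features
  z <- normalize_features(matrix(f[signature], 1,
                                 dimnames = list(NULL, signature)),
                          stats = norm)$x
  pr <- predict_classifier(model, z)
  list(grade = as.integer(pr$labels), scores = pr$scores)
}
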