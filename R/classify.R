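#' Per-unit feature table along histology strips
#'
#' Divides each strip into a row of adjacent `unit_px` x `unit_px` unit
#' regions and extracts the mean retardance, depolarization, hue and
#' saturation of every unit together with its pathology label.  Three strips
#' of 22 units give the canonical 66-sample table.
#'
#' @param maps named list with matrices (or [parameter_map()]s) `retardance`
#'   and `depolarization`, plus `hue` and `saturation`.
#' @param strips data frame with one row per strip: `row`, `col` (top-left
#'   pixel of the first unit, 1-based) and `n_units`.
#' @param labels list (one vector per strip) or single vector of per-unit
#'   labels, values `"cancer"`/`"normal"` (SCC and dysplasia versus normal).
#' @param unit_px unit size in pixels.
#' @return data frame with columns `strip_id`, `unit_id`, `ret`, `dep`,
#'   `hue`, `sat`, `label`.
#' @export
build_feature_table <- function(maps, strips, labels, unit_px = 30L) {
  as_mat <- function(x) if (inherits(x, "parameter_map")) x$values else x
  m <- lapply(maps[c("retardance", "depolarization", "hue", "saturation")],
              as_mat)
  if (is.list(labels)) labels <- unlist(labels, use.names = FALSE)
  total <- sum(strips$n_units)
  if (length(labels) != total)
    stop(sprintf("expected %d unit labels, got %d", total, length(labels)))

  rows <- vector("list", total)
  n <- 0L
  for (s in seq_len(nrow(strips))) {
    for (u in seq_len(strips$n_units[s])) {
      ri <- strips$row[s] + 0:(unit_px - 1L)
      ci <- strips$col[s] + (u - 1L) * unit_px + 0:(unit_px - 1L)
      if (max(ri) > nrow(m$retardance) || max(ci) > ncol(m$retardance))
        stop("strip extends beyond the image")
      n <- n + 1L
      rows[[n]] <- data.frame(
        strip_id = s, unit_id = u,
        ret = mean(m$retardance[ri, ci]),
        dep = mean(m$depolarization[ri, ci]),
        hue = mean(m$hue[ri, ci]),
        sat = mean(m$saturation[ri, ci]),
        label = labels[n])
    }
  }
  do.call(rbind, rows)
}

feature_subsets <- list(
  colour    = c("hue", "sat"),
  ret       = "ret",
  dep       = "dep",
  `ret+dep` = c("ret", "dep"),
  joint     = c("ret", "dep", "hue", "sat")
)

#' Linear-SVM tissue classification with ROC/AUC
#'
#' Fits a linear-kernel support vector machine on a seeded random 0.6/0.4
#' train/test split of the feature table and evaluates it on the held-out
#' part: the ROC curve is swept over the decision-function threshold and
#' summarized by its AUC; sensitivity and specificity are reported at the
#' fitted boundary (decision value 0).  Features are z-standardized using
#' training-split statistics.  If a split leaves a single class on either
#' side it is redrawn with the next seed (with a warning).
#'
#' @param table a [build_feature_table()] result.
#' @param feature_subset one of `"colour"`, `"ret"`, `"dep"`, `"ret+dep"`,
#'   `"joint"`.
#' @param split training fraction.
#' @param seed integer seed for the split.
#' @param cost SVM regularization parameter C.
#' @return list of class `"classification_report"` with `auc`, `roc`
#'   (data frame of ROC points), `sensitivity`, `specificity`,
#'   `feature_subset`, `train_idx`, `test_idx`, `seed`, `cost`.
#' @export
svm_classify <- function(table, feature_subset = "joint", split = 0.6,
                         seed = 1L, cost = 1.0) {
  feature_subset <- match.arg(feature_subset, names(feature_subsets))
  feats <- feature_subsets[[feature_subset]]
  y <- factor(table$label, levels = c("normal", "cancer"))
  if (nlevels(droplevels(y)) < 2L) stop("both classes must be present")
  X <- as.matrix(table[, feats, drop = FALSE])
  n <- nrow(X)

  for (try in 0:24) {
    set.seed(seed + try)
    train <- sort(sample.int(n, round(split * n)))
    test <- setdiff(seq_len(n), train)
    if (nlevels(droplevels(y[train])) == 2L &&
        nlevels(droplevels(y[test])) == 2L) {
      if (try > 0) warning(sprintf("single-class split; used seed %d",
                                   seed + try))
      break
    }
    if (try == 24) stop("could not find a two-class split")
  }

  mu <- colMeans(X[train, , drop = FALSE])
  sdv <- apply(X[train, , drop = FALSE], 2, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")

  fit <- e1071::svm(Z[train, , drop = FALSE], y[train], kernel = "linear",
                    cost = cost, scale = FALSE)
  pred <- stats::predict(fit, Z[test, , drop = FALSE],
                         decision.values = TRUE)
  dec <- as.numeric(attr(pred, "decision.values"))
  # orient the decision value so that larger means more cancer-like
  pos_first <- strsplit(colnames(attr(pred, "decision.values")), "/")[[1]][1]
  if (pos_first != "cancer") dec <- -dec

  roc <- pROC::roc(response = y[test], predictor = dec,
                   levels = c("normal", "cancer"), direction = "<",
                   quiet = TRUE)
  is_cancer <- y[test] == "cancer"
  structure(list(
    feature_subset = feature_subset,
    auc = as.numeric(pROC::auc(roc)),
    roc = data.frame(fpr = 1 - roc$specificities, tpr = roc$sensitivities),
    sensitivity = mean(dec[is_cancer] > 0),
    specificity = mean(dec[!is_cancer] <= 0),
    train_idx = train, test_idx = test, seed = seed, cost = cost
  ), class = "classification_report")
}

#' Simulated strip-sampling classification study
#'
#' Runs the whole ex-vivo-style analysis on a synthetic larynx scene wide
#' enough to carry strips of adjacent square unit regions: simulates the
#' snapshot acquisition in both modes (shot + read noise), reconstructs the
#' retardance and circular-depolarization maps, derives hue/saturation from
#' the synthetic colour photograph, samples `n_units` units of
#' `unit_px` x `unit_px` pixels along each strip and labels every unit by
#' the majority ground-truth class.
#'
#' @param seed integer seed driving the scene, the acquisition noise and
#'   nothing else.
#' @param shape scene dimensions; the default fits 3 strips of 22 units of
#'   30 px.
#' @param strips data frame with `row`, `col`, `n_units` per strip.
#' @param unit_px unit size in pixels.
#' @param exposure_scale,noise acquisition settings
#'   (see [simulate_dofp_mosaic()]).
#' @param n_lesions number of cancerous lesions in the scene.
#' @return list with the feature `table`, the `scene` and the reconstructed
#'   `maps`.
#' @export
larynx_feature_study <- function(seed = 1L, shape = c(128L, 672L),
                                 strips = data.frame(row = c(10, 50, 90),
                                                     col = 6,
                                                     n_units = 22),
                                 unit_px = 30L, exposure_scale = 255,
                                 noise = list(shot = TRUE, read_sd = 1),
                                 n_lesions = 4L) {
  scene <- make_larynx_scene(shape, seed = seed, n_lesions = n_lesions)
  si <- scene_to_stokes(scene$truth)
  maps <- list()
  for (mode in c("retardance", "depolarization")) {
    mos <- simulate_dofp_mosaic(si, mode = mode,
                                exposure_scale = exposure_scale,
                                noise = noise,
                                seed = substream_seed(seed,
                                                      paste0("study_", mode)))
    sub <- demosaic_bilinear(mos)
    ps <- if (mode == "retardance") partial_stokes_linear(sub)
          else partial_stokes_circular(sub)
    ok <- exposure_mask(ps$S0, attr(mos, "bitdepth"))
    maps[[mode]] <- if (mode == "retardance") retardance_map(ps, ok)
                    else depolarization_map(ps, ok)
  }
  hs <- hue_saturation_from_rgb(scene_to_rgb(scene))

  labels <- character(0)
  for (s in seq_len(nrow(strips))) {
    for (u in seq_len(strips$n_units[s])) {
      ri <- strips$row[s] + 0:(unit_px - 1L)
      ci <- strips$col[s] + (u - 1L) * unit_px + 0:(unit_px - 1L)
      frac_cancer <- mean(scene$truth$labels[ri, ci] == 2L)
      labels <- c(labels, if (frac_cancer > 0.5) "cancer" else "normal")
    }
  }
  table <- build_feature_table(
    list(retardance = maps$retardance, depolarization = maps$depolarization,
         hue = hs$hue, saturation = hs$saturation),
    strips, labels, unit_px = unit_px)
  list(table = table, scene = scene, maps = maps)
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report %s> AUC=%.3f sens=%.3f spec=%.3f (n_test=%d)\n",
              x$feature_subset, x$auc, x$sensitivity, x$specificity,
              length(x$test_idx)))
  invisible(x)
}
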