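## Two-stage random-forest conformation classifier.
##
## Stage 1 assigns the DFG class (in / out / intermediate) from the eight
## normalized descriptors; stage 2 assigns the alphaC class (in / out) from
## the descriptors plus the DFG class encoded as three indicator columns.
## The (DFG, alphaC) pair maps onto the five conformations; rows with a
## distorted (intermediate) DFG motif are wCD and bypass stage 2.

#' Combine stage labels into a conformation label
#'
#' `(in, in) -> CIDI`, `(out, in) -> CIDO`, `(in, out) -> CODI`,
#' `(out, out) -> CODO`; any row with DFG `intermediate` is `wCD`
#' regardless of the alphaC class (which may be NA).
#'
#' @param dfg_class Character vector over `{"in", "out", "intermediate"}`.
#' @param ac_class Character vector over `{"in", "out"}` (NA allowed where
#'   `dfg_class` is `"intermediate"`).
#' @return Character vector of conformation labels.
#' @export
combine_labels <- function(dfg_class, ac_class) {
  stopifnot(length(dfg_class) == length(ac_class))
  if (!all(dfg_class %in% DFG_LEVELS)) {
    stop("dfg_class must be one of: ", paste(DFG_LEVELS, collapse = ", "),
         call. = FALSE)
  }
  inter <- dfg_class == "intermediate"
  if (!all(ac_class[!inter] %in% AC_LEVELS)) {
    stop("ac_class must be one of: ", paste(AC_LEVELS, collapse = ", "),
         call. = FALSE)
  }
  out <- character(length(dfg_class))
  out[inter] <- "wCD"
  out[!inter] <- ifelse(
    dfg_class[!inter] == "in",
    ifelse(ac_class[!inter] == "in", "CIDI", "CODI"),
    ifelse(ac_class[!inter] == "in", "CIDO", "CODO")
  )
  out
}

## Inverse of combine_labels: conformation -> (dfg, ac); wCD has no
## defined alphaC state.
split_conformation <- function(conformation) {
  stopifnot(all(conformation %in% CONFORMATION_LEVELS))
  dfg <- dplyr::case_match(conformation,
                           c("CIDI", "CODI") ~ "in",
                           c("CIDO", "CODO") ~ "out",
                           "wCD" ~ "intermediate")
  ac <- dplyr::case_match(conformation,
                          c("CIDI", "CIDO") ~ "in",
                          c("CODI", "CODO") ~ "out",
                          "wCD" ~ NA_character_)
  tibble::tibble(dfg_class = dfg, ac_class = ac)
}

#' Proximity-based imputation of missing descriptor values
#'
#' Missing cells are initialized with the per-class column median, then
#' refined for a fixed number of iterations: a random forest is fit on the
#' current table, pairwise proximities (fraction of trees in which two rows
#' share a terminal node) are computed, and each missing cell is replaced
#' by the proximity-weighted average of the observed values in its column.
#' Deterministic given `seed`.
#'
#' @param data Data frame with the eight descriptor columns (NA = missing);
#'   extra columns are carried through untouched.
#' @param labels Class labels aligned with rows (used for the per-class
#'   median initialization and as the forest response).
#' @param n_iter Number of refinement iterations (default 5).
#' @param n_trees Trees per refinement forest (default 300).
#' @param seed Integer seed.
#' @return `data` with descriptor NAs filled in.
#' @export
impute_missing <- function(data, labels, n_iter = 5, n_trees = 300, seed = 1) {
  stopifnot(is.data.frame(data), all(DESCRIPTOR_NAMES %in% names(data)),
            length(labels) == nrow(data))
  x <- as.matrix(as.data.frame(data)[, DESCRIPTOR_NAMES])
  if (any(colSums(!is.na(x)) == 0)) {
    stop("cannot impute a fully-missing descriptor column", call. = FALSE)
  }
  na_mask <- is.na(x)
  out <- tibble::as_tibble(data)
  if (!any(na_mask)) return(out)

  labels <- factor(labels)
  filled <- x
  for (j in seq_len(ncol(x))) {
    if (!any(na_mask[, j])) next
    med_all <- median(x[, j], na.rm = TRUE)
    for (cl in levels(labels)) {
      rows <- which(labels == cl & na_mask[, j])
      if (length(rows) == 0) next
      med <- median(x[labels == cl, j], na.rm = TRUE)
      filled[rows, j] <- if (is.na(med)) med_all else med
    }
  }

  for (it in seq_len(n_iter)) {
    ## the forest needs at least one splittable column; with none, the
    ## proximity-weighted average would reproduce the initialization anyway
    varying <- which(apply(filled, 2, function(v) diff(range(v)) > 0))
    if (length(varying) == 0) break
    set.seed(seed + it)
    rf <- if (nlevels(labels) >= 2) {
      randomForest::randomForest(x = filled[, varying, drop = FALSE],
                                 y = labels, ntree = n_trees,
                                 proximity = TRUE)
    } else {
      # single class: unsupervised forest still yields proximities
      randomForest::randomForest(x = filled[, varying, drop = FALSE],
                                 ntree = n_trees, proximity = TRUE)
    }
    prox <- rf$proximity
    diag(prox) <- 0
    for (j in seq_len(ncol(x))) {
      miss <- which(na_mask[, j])
      if (length(miss) == 0) next
      obs <- which(!na_mask[, j])
      for (i in miss) {
        w <- prox[i, obs]
        if (sum(w) > 0) filled[i, j] <- sum(w * x[obs, j]) / sum(w)
      }
    }
  }
  for (d in DESCRIPTOR_NAMES) out[[d]] <- filled[, d]
  out
}

#' Train the two-stage conformation classifier
#'
#' Imputes missing descriptors, fits the (-1, 1) normalization, then trains
#' the stage-1 DFG forest and the stage-2 alphaC forest. Rows with DFG
#' `intermediate` are excluded from stage-2 training (their alphaC state is
#' by definition distorted). Out-of-bag (OOB) errors are reported per stage
#' and for the combined five-class prediction.
#'
#' @param data Data frame with the eight descriptor columns plus either
#'   `dfg_class` and `ac_class` columns or a `conformation` column (from
#'   which the stage labels are derived).
#' @param n_trees Trees per stage (default 1000).
#' @param seed Integer seed; training is reproducible bit-for-bit.
#' @param impute_iter Iterations for [impute_missing()] (default 5).
#' @return A `conf_forest` model object; see [predict.conf_forest()],
#'   [tidy.conf_forest()] and [glance.conf_forest()].
#' @export
train_conformation_forest <- function(data, n_trees = 1000, seed = 1,
                                      impute_iter = 5) {
  stopifnot(is.data.frame(data), all(DESCRIPTOR_NAMES %in% names(data)))
  if (!all(c("dfg_class", "ac_class") %in% names(data))) {
    if (!"conformation" %in% names(data)) {
      stop("data needs dfg_class/ac_class columns or a conformation column",
           call. = FALSE)
    }
    data <- dplyr::bind_cols(
      data[setdiff(names(data), c("dfg_class", "ac_class"))],
      split_conformation(data$conformation)
    )
  }
  dfg <- factor(data$dfg_class, levels = DFG_LEVELS)
  ac <- factor(data$ac_class, levels = AC_LEVELS)
  if (anyNA(dfg)) stop("invalid dfg_class values", call. = FALSE)
  if (dplyr::n_distinct(dfg) < 2) {
    stop("stage 1 needs at least two DFG classes", call. = FALSE)
  }
  stage2_rows <- which(dfg != "intermediate")
  if (dplyr::n_distinct(ac[stage2_rows]) < 2) {
    stop("stage 2 needs at least two alphaC classes", call. = FALSE)
  }
  if (anyNA(ac[stage2_rows])) {
    stop("ac_class missing on a non-intermediate row", call. = FALSE)
  }
  conf <- combine_labels(as.character(dfg), as.character(ac))

  imputed <- impute_missing(data, conf, n_iter = impute_iter, seed = seed)
  ranges <- fit_normalization(imputed)
  norm <- normalize_descriptors(imputed, ranges)
  x <- as.matrix(as.data.frame(norm)[, DESCRIPTOR_NAMES])

  dfg <- droplevels(dfg)
  set.seed(seed)
  stage1 <- randomForest::randomForest(x = x, y = dfg, ntree = n_trees,
                                       importance = TRUE)

  x2 <- cbind(x[stage2_rows, , drop = FALSE],
              dfg_indicator(as.character(dfg[stage2_rows])))
  set.seed(seed + 1L)
  stage2 <- randomForest::randomForest(x = x2, y = droplevels(ac[stage2_rows]),
                                       ntree = n_trees, importance = TRUE)

  ## Combined five-class OOB prediction: stage-1 OOB call decides the DFG
  ## branch; non-intermediate rows then take their stage-2 OOB call.
  s1_pred <- as.character(stage1$predicted)
  pred5 <- rep("wCD", nrow(x))
  s2_pred <- rep(NA_character_, nrow(x))
  s2_pred[stage2_rows] <- as.character(stage2$predicted)
  nonint <- s1_pred != "intermediate"
  pred5[nonint] <- combine_labels(
    s1_pred[nonint],
    ifelse(is.na(s2_pred[nonint]), "in", s2_pred[nonint])
  )
  oob <- list(
    stage1 = mean(s1_pred != as.character(dfg)),
    stage2 = mean(s2_pred[stage2_rows] != as.character(ac[stage2_rows])),
    overall = mean(pred5 != conf)
  )

  structure(
    list(stage1 = stage1, stage2 = stage2, ranges = ranges,
         training_x = x, training_medians = apply(x, 2, median),
         seed = seed, n_trees = n_trees, oob = oob,
         n_per_class = table(factor(conf, levels = CONFORMATION_LEVELS)),
         version = 1L),
    class = "conf_forest"
  )
}

dfg_indicator <- function(dfg_class) {
  m <- cbind(
    dfg_in = as.numeric(dfg_class == "in"),
    dfg_out = as.numeric(dfg_class == "out"),
    dfg_intermediate = as.numeric(dfg_class == "intermediate")
  )
  m
}

#' @export
print.conf_forest <- function(x, ...) {
  cat("<conf_forest> two-stage random forest,", x$n_trees, "trees/stage\n")
  cat("  training:", paste(names(x$n_per_class), as.integer(x$n_per_class),
                           sep = "=", collapse = ", "), "\n")
  cat(sprintf("  OOB error: DFG stage %.3f, alphaC stage %.3f, 5-class %.3f\n",
              x$oob$stage1, x$oob$stage2, x$oob$overall))
  invisible(x)
}

## Prediction-time imputation: fill missing normalized descriptors with the
## proximity-weighted (terminal nodes of the stage-1 forest) average of the
## training rows; all-missing rows fall back to training medians.
impute_for_prediction <- function(model, xnorm) {
  na_mask <- is.na(xnorm)
  low_conf <- apply(na_mask, 1, all)
  if (!any(na_mask)) return(list(x = xnorm, low_confidence = low_conf))
  filled <- xnorm
  for (j in seq_len(ncol(filled))) {
    filled[is.na(filled[, j]), j] <- model$training_medians[j]
  }
  train_nodes <- attr(predict(model$stage1, model$training_x, nodes = TRUE),
                      "nodes")
  query_nodes <- attr(predict(model$stage1, filled, nodes = TRUE), "nodes")
  for (i in which(apply(na_mask, 1, any) & !low_conf)) {
    prox <- rowMeans(train_nodes == matrix(query_nodes[i, ],
                                           nrow(train_nodes),
                                           ncol(train_nodes), byrow = TRUE))
    for (j in which(na_mask[i, ])) {
      if (sum(prox) > 0) {
        filled[i, j] <- sum(prox * model$training_x[, j]) / sum(prox)
      }
    }
  }
  list(x = filled, low_confidence = low_conf)
}

#' Predict kinase conformations
#'
#' New descriptor vectors are normalized with clamping, missing entries are
#' imputed by proximity to the training rows, and the stage probabilities
#' are combined into five-class probabilities:
#' `P(wCD) = P(DFG-intermediate)`, and for the four main classes
#' `P(conformation) = P(DFG branch) * P(alphaC branch | DFG branch)`.
#'
#' @param object A `conf_forest`.
#' @param newdata Data frame with the eight descriptor columns (raw scale;
#'   NA = missing).
#' @param ... Unused.
#' @return A `conf_prediction` tibble: `label`, five class probabilities
#'   (`p_cidi`, `p_cido`, `p_codi`, `p_codo`, `p_wcd`), the stage
#'   probabilities, and `low_confidence` (TRUE for all-missing input).
#' @export
predict.conf_forest <- function(object, newdata, ...) {
  stopifnot(inherits(object, "conf_forest"))
  if (is.null(object$stage1)) stop("model is not trained", call. = FALSE)
  stopifnot(is.data.frame(newdata), all(DESCRIPTOR_NAMES %in% names(newdata)))
  norm <- normalize_descriptors(newdata, object$ranges)
  xnorm <- as.matrix(as.data.frame(norm)[, DESCRIPTOR_NAMES])
  imp <- impute_for_prediction(object, xnorm)
  x <- imp$x

  p1 <- predict(object$stage1, x, type = "prob")
  p_dfg <- matrix(0, nrow(x), 3,
                  dimnames = list(NULL, DFG_LEVELS))
  p_dfg[, colnames(p1)] <- p1

  p_ac_given <- lapply(c("in", "out"), function(g) {
    x2 <- cbind(x, dfg_indicator(rep(g, nrow(x))))
    p2 <- predict(object$stage2, x2, type = "prob")
    m <- matrix(0, nrow(x), 2, dimnames = list(NULL, AC_LEVELS))
    m[, colnames(p2)] <- p2
    m
  })
  names(p_ac_given) <- c("in", "out")

  probs <- cbind(
    CIDI = p_dfg[, "in"] * p_ac_given[["in"]][, "in"],
    CIDO = p_dfg[, "out"] * p_ac_given[["out"]][, "in"],
    CODI = p_dfg[, "in"] * p_ac_given[["in"]][, "out"],
    CODO = p_dfg[, "out"] * p_ac_given[["out"]][, "out"],
    wCD = p_dfg[, "intermediate"]
  )
  probs <- probs / rowSums(probs)
  probs <- probs[, CONFORMATION_LEVELS, drop = FALSE]
  label <- CONFORMATION_LEVELS[apply(probs, 1, which.max)]

  ## marginal alphaC probabilities over the non-intermediate branches
  p_ac_in <- p_dfg[, "in"] * p_ac_given[["in"]][, "in"] +
    p_dfg[, "out"] * p_ac_given[["out"]][, "in"]
  denom <- pmax(p_dfg[, "in"] + p_dfg[, "out"], 1e-12)

  out <- tibble::tibble(
    label = label,
    p_cidi = probs[, "CIDI"], p_cido = probs[, "CIDO"],
    p_codi = probs[, "CODI"], p_codo = probs[, "CODO"],
    p_wcd = probs[, "wCD"],
    p_dfg_in = p_dfg[, "in"], p_dfg_out = p_dfg[, "out"],
    p_dfg_intermediate = p_dfg[, "intermediate"],
    p_ac_in = p_ac_in / denom, p_ac_out = 1 - p_ac_in / denom,
    low_confidence = imp$low_confidence
  )
  class(out) <- c("conf_prediction", class(out))
  out
}

#' @describeIn train_conformation_forest Per-feature importance of both
#'   stages as a tidy tibble (`stage`, `term`, `importance` =
#'   mean decrease in Gini impurity).
#' @param x A `conf_forest`.
#' @export
tidy.conf_forest <- function(x, ...) {
  imp <- function(rf, stage) {
    m <- randomForest::importance(rf, type = 2)
    tibble::tibble(stage = stage, term = rownames(m),
                   importance = as.numeric(m[, 1]))
  }
  dplyr::bind_rows(imp(x$stage1, "dfg"), imp(x$stage2, "alphac"))
}

#' @describeIn train_conformation_forest One-row model summary (training
#'   sizes and out-of-bag errors).
#' @export
glance.conf_forest <- function(x, ...) {
  tibble::tibble(
    n = sum(x$n_per_class), n_trees = x$n_trees, seed = x$seed,
    oob_dfg = x$oob$stage1, oob_alphac = x$oob$stage2,
    oob_overall = x$oob$overall
  )
}

#' Save / load a trained conformation classifier
#'
#' The archive is versioned; loading refuses a version mismatch.
#'
#' @param model A `conf_forest`.
#' @param path File path.
#' @return `save_conf_forest` returns `path` invisibly;
#'   `load_conf_forest` returns the model.
#' @export
save_conf_forest <- function(model, path) {
  stopifnot(inherits(model, "conf_forest"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_conf_forest
#' @export
load_conf_forest <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "conf_forest") || !identical(model$version, 1L)) {
    stop("not a compatible conf_forest archive (version mismatch)",
         call. = FALSE)
  }
  model
}
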