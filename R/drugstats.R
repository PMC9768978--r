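#' Assemble a dose-response parameter table
#'
#' Stacks per-well burst panels (one row each, see [compute_metrics()])
#' into a tidy table keyed by sample, condition and concentration —
#' the input for the Dunnett heat map, the PCA and the pairwise MANOVA.
#'
#' @param metrics A data frame (or list of one-row data frames) holding
#'   the ten burst-panel columns.
#' @param sample_id,condition,concentration Vectors, one value per row of
#'   `metrics` (recycled if length 1).
#' @return Tibble with `sample_id`, `condition`, `concentration` followed
#'   by the ten metric columns, ordered by condition then sample.
#'   `NaN`-flagged metrics are converted to `NA` (missing cells).
#' @export
build_param_table <- function(metrics, sample_id, condition,
                              concentration = NA_real_) {
  if (is.list(metrics) && !is.data.frame(metrics)) {
    metrics <- dplyr::bind_rows(metrics)
  }
  miss <- setdiff(burst_metric_names(), names(metrics))
  if (length(miss)) {
    stop("metrics lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    sample_id = rep_len(sample_id, nrow(metrics)),
    condition = as.character(rep_len(condition, nrow(metrics))),
    concentration = rep_len(concentration, nrow(metrics))
  )
  out <- dplyr::bind_cols(out, metrics[burst_metric_names()])
  if (anyNA(out$condition)) stop("missing condition labels", call. = FALSE)
  key <- paste(out$sample_id, out$condition, out$concentration)
  if (anyDuplicated(key)) {
    stop("duplicate (sample, condition, concentration) rows", call. = FALSE)
  }
  for (m in burst_metric_names()) out[[m]][is.nan(out[[m]])] <- NA_real_
  out[order(out$condition, out$concentration, out$sample_id), ]
}

# Run code with a locally fixed RNG seed, restoring the caller's RNG
# state afterwards. Used to freeze the randomized quantile integration
# behind the Dunnett adjustment.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' One-way ANOVA with Dunnett's many-to-one comparisons
#'
#' For one parameter, fits a one-way ANOVA across conditions and compares
#' every non-control group with the control using Dunnett's test
#' (multivariate-t adjustment via \pkg{multcomp}). The randomized quantile
#' integration is run under a fixed internal seed so results are
#' reproducible; the caller's RNG state is untouched. Missing cells are
#' dropped with a count.
#'
#' @param table Parameter table from [build_param_table()].
#' @param parameter Name of the metric column to test.
#' @param control Condition label of the vehicle/control group.
#' @return Tibble with one row per non-control condition: `parameter`,
#'   `condition`, `concentration`, `estimate` (difference vs control),
#'   `direction` (-1/0/+1), `p_adj`, `tier` (`""`, `"*"` p<0.05, `"**"`
#'   p<0.01), plus attributes `f_value`, `p_anova`, `n_missing`.
#' @export
anova_dunnett <- function(table, parameter, control) {
  if (!parameter %in% names(table)) {
    stop("unknown parameter: ", parameter, call. = FALSE)
  }
  if (!control %in% table$condition) {
    stop("control condition '", control, "' not present", call. = FALSE)
  }
  d <- table[, c("condition", "concentration", parameter)]
  names(d)[3] <- "y"
  n_missing <- sum(is.na(d$y))
  d <- d[!is.na(d$y), ]
  lv <- c(control, setdiff(unique(d$condition), control))
  d$g <- factor(d$condition, levels = lv)
  tab <- table(d$g)
  if (length(tab) < 2 || any(tab < 2)) {
    stop("need >= 2 groups with n >= 2 each for ", parameter, call. = FALSE)
  }
  if (stats::var(d$y) == 0) {
    # all observations identical: no evidence of any effect
    out <- dplyr::distinct(d[d$condition != control,
                             c("condition", "concentration")])
    res <- tibble::tibble(parameter = parameter,
                          condition = out$condition,
                          concentration = out$concentration,
                          estimate = 0, direction = 0, p_adj = 1, tier = "")
    attr(res, "f_value") <- 0; attr(res, "p_anova") <- 1
    attr(res, "n_missing") <- n_missing
    return(res)
  }
  fit <- stats::aov(y ~ g, data = d)
  an <- summary(fit)[[1]]
  gl <- with_local_seed(20221220L, {
    summary(multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett")))
  })
  est <- unname(gl$test$coefficients)
  p <- unname(gl$test$pvalues)
  comp <- sub(" - .*$", "", names(gl$test$coefficients))
  conc <- vapply(comp, function(cc) {
    u <- unique(d$concentration[d$condition == cc])
    if (length(u) == 1) u[1] else NA_real_
  }, numeric(1))
  res <- tibble::tibble(
    parameter = parameter,
    condition = comp,
    concentration = conc,
    estimate = est,
    direction = sign(est),
    p_adj = pmin(pmax(p, .Machine$double.eps), 1),
    tier = ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
  )
  attr(res, "f_value") <- an$`F value`[1]
  attr(res, "p_anova") <- an$`Pr(>F)`[1]
  attr(res, "n_missing") <- n_missing
  res
}

#' Dunnett heat map over the ten-parameter panel
#'
#' Runs [anova_dunnett()] for every parameter of the panel (or a chosen
#' subset) and stacks the rows — the tabular form of the
#' parameter-by-condition significance heat map.
#'
#' @param table Parameter table.
#' @param control Control condition label.
#' @param parameters Metric columns to test (default: all ten).
#' @return Tibble of [anova_dunnett()] rows for all parameters.
#' @export
dunnett_heatmap <- function(table, control,
                            parameters = burst_metric_names()) {
  purrr::map_dfr(parameters, function(p) anova_dunnett(table, p, control))
}

#' @rdname dunnett_heatmap
#' @param heatmap Result of `dunnett_heatmap()`.
#' @return `plot_dunnett_heatmap()`: a ggplot tile map of signed
#'   significance.
#' @export
plot_dunnett_heatmap <- function(heatmap) {
  heatmap$signed <- heatmap$direction * -log10(heatmap$p_adj)
  heatmap$label <- heatmap$tier
  ggplot2::ggplot(heatmap, ggplot2::aes(
    x = factor(.data$concentration), y = .data$parameter,
    fill = .data$signed)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label)) +
    ggplot2::scale_fill_gradient2(low = "navy", high = "firebrick",
                                  name = "sign x -log10(p)") +
    ggplot2::labs(x = "concentration", y = NULL)
}

#' Principal component analysis of the five-parameter set
#'
#' PCA of the dose-response table restricted to the five parameters used
#' for compound discrimination: total spike count, mean NB duration, mean
#' IMFI, CV of NB duration and CV of spikes per NB. Columns are z-scored
#' (the parameters have incommensurate units), the correlation structure
#' is eigendecomposed, and scores on the first two components are
#' returned. Signs are fixed so each component's largest-magnitude
#' loading is positive. Zero-variance columns are dropped with a warning;
#' rows with missing cells are dropped with a count.
#'
#' @param table Parameter table from [build_param_table()].
#' @param parameters The columns to use (default: the five-parameter set).
#' @return Object of class `mea_pca`: list with `loadings`, `explained`
#'   (variance fractions), `scores` (tibble with `sample_id`, `condition`,
#'   `concentration`, `PC1`, `PC2`), `dropped_columns`, `n_dropped_rows`.
#'   Supports `tidy()`, `glance()` and `autoplot()`.
#' @export
pca5 <- function(table,
                 parameters = c("total_spikes", "mean_nb_duration_s",
                                "mean_imfi_s", "cv_nb_duration",
                                "cv_spikes_per_nb")) {
  miss <- setdiff(parameters, names(table))
  if (length(miss)) stop("table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  X <- as.matrix(table[, parameters])
  keep_row <- stats::complete.cases(X)
  X <- X[keep_row, , drop = FALSE]
  if (nrow(X) < 3) stop("need >= 3 complete rows for PCA", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  dropped <- parameters[sds == 0]
  if (length(dropped)) {
    warning("dropping zero-variance column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  Z <- scale(X)
  eg <- eigen(stats::cor(X), symmetric = TRUE)
  load <- eg$vectors
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  rownames(load) <- colnames(X)
  colnames(load) <- paste0("PC", seq_len(ncol(load)))
  scores <- Z %*% load
  sc <- tibble::tibble(
    sample_id = table$sample_id[keep_row],
    condition = table$condition[keep_row],
    concentration = table$concentration[keep_row],
    PC1 = scores[, 1],
    PC2 = if (ncol(scores) >= 2) scores[, 2] else 0
  )
  structure(list(
    loadings = load,
    explained = pmax(eg$values, 0) / sum(pmax(eg$values, 0)),
    scores = sc,
    all_scores = scores,
    dropped_columns = dropped,
    n_dropped_rows = sum(!keep_row)
  ), class = "mea_pca")
}

#' @export
print.mea_pca <- function(x, ...) {
  cat(sprintf("<mea_pca> %d rows, %d components; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), length(x$explained),
              100 * x$explained[1],
              if (length(x$explained) > 1) 100 * x$explained[2] else 0))
  invisible(x)
}

#' @export
tidy.mea_pca <- function(x, ...) {
  d <- tibble::as_tibble(x$loadings, rownames = "parameter")
  tidyr::pivot_longer(d, -"parameter", names_to = "component",
                      values_to = "loading")
}

#' @export
glance.mea_pca <- function(x, ...) {
  tibble::tibble(component = paste0("PC", seq_along(x$explained)),
                 explained_variance = x$explained)
}

#' @export
autoplot.mea_pca <- function(object, ...) {
  ggplot2::ggplot(object$scores, ggplot2::aes(
    .data$PC1, .data$PC2, colour = .data$condition)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained[2]))
}

#' Pairwise MANOVA on PCA scores
#'
#' One-way MANOVA (Wilks' lambda with its F approximation) on the
#' two-dimensional PCA scores for every pair of conditions — the test
#' used to ask whether two compounds produce distinguishable
#' multiparameter response signatures.
#'
#' @param scores Tibble with `condition`, `PC1`, `PC2` (e.g.
#'   `pca5(...)$scores`).
#' @return List with `p_matrix` (symmetric, `NA` diagonal) and `tidy`
#'   (tibble `condition_a`, `condition_b`, `wilks`, `p_value`).
#' @export
manova_pairwise <- function(scores) {
  gs <- sort(unique(scores$condition))
  if (length(gs) < 2) stop("need >= 2 conditions", call. = FALSE)
  cnt <- table(scores$condition)
  if (any(cnt < 3)) {
    stop("every condition needs n >= 3 (2-dimensional scores): ",
         paste(names(cnt)[cnt < 3], collapse = ", "), call. = FALSE)
  }
  pm <- matrix(NA_real_, length(gs), length(gs), dimnames = list(gs, gs))
  rows <- list()
  for (i in seq_along(gs)) for (j in seq_along(gs)) if (i < j) {
    d <- scores[scores$condition %in% c(gs[i], gs[j]), ]
    Y <- cbind(d$PC1, d$PC2)
    fit <- tryCatch(
      summary(stats::manova(Y ~ factor(d$condition)), test = "Wilks"),
      error = function(e) {
        stop("MANOVA failed for pair (", gs[i], ", ", gs[j], "): ",
             conditionMessage(e), call. = FALSE)
      })
    st <- fit$stats
    pm[i, j] <- pm[j, i] <- st[1, "Pr(>F)"]
    rows[[length(rows) + 1]] <- tibble::tibble(
      condition_a = gs[i], condition_b = gs[j],
      wilks = st[1, "Wilks"], p_value = st[1, "Pr(>F)"])
  }
  list(p_matrix = pm, tidy = dplyr::bind_rows(rows))
}

#' Two-tailed paired t-test
#'
#' Paired comparison of a quantity measured before and after an
#' intervention on the same preparations (e.g. the band statistic before
#' and after theta-burst stimulation). When all paired differences are
#' identical the test is degenerate: `p = 1` if the common difference is
#' zero, `p = 0` otherwise.
#'
#' @param pre,post Numeric vectors of equal length (>= 2).
#' @return One-row tibble `mean_diff`, `t`, `df`, `p_value`, `n`.
#' @export
paired_t <- function(pre, post) {
  if (length(pre) != length(post)) {
    stop("pre and post differ in length", call. = FALSE)
  }
  if (length(pre) < 2) stop("need >= 2 pairs", call. = FALSE)
  d <- post - pre
  # degenerate when the differences are constant to machine precision
  if (stats::sd(d) <= 1e-10 * max(1, abs(mean(d)))) {
    return(tibble::tibble(
      mean_diff = mean(d),
      t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
      df = length(d) - 1,
      p_value = if (mean(d) == 0) 1 else 0,
      n = length(d)))
  }
  tt <- stats::t.test(post, pre, paired = TRUE)
  tibble::tibble(mean_diff = unname(tt$estimate), t = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value,
                 n = length(d))
}
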