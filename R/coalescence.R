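#' Neutral (mass-effects) prediction of post-coalescence composition
#'
#' Under pure mass effects the composition after mixing equal volumes of all
#' microcosms is the cell-count-weighted mean of the source compositions:
#' \deqn{\hat p_G = \frac{\sum_i rel.reads_{G,i} \times cells_i}{\sum_i cells_i}}
#' so the predictions sum to 1 over genera by construction.
#'
#' @param table_c6 Abundance table of the final pre-coalescence cycle.
#' @param cell_counts Named numeric vector of per-microcosm cell counts
#'   (names matching the microcosm columns), all positive.
#' @return A tibble: `genus`, `prediction` (relative abundance, sums to 1).
#' @export
#' @examples
#' tab <- abundance_table(matrix(c(10, 0, 0, 10), 2, 2,
#'   dimnames = list(c("gA", "gB"), c("m1", "m2"))))
#' predict_neutral(tab, c(m1 = 9e6, m2 = 1e6)) # gA 0.9, gB 0.1
predict_neutral <- function(table_c6, cell_counts) {
  m <- count_matrix(table_c6)
  miss <- setdiff(colnames(m), names(cell_counts))
  if (length(miss) > 0) {
    stop("missing cell count for microcosm(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  cells <- cell_counts[colnames(m)]
  if (any(!is.finite(cells)) || any(cells <= 0)) {
    stop("cell counts must be positive for every microcosm", call. = FALSE)
  }
  rel <- sweep(m, 2, colSums(m), "/")
  pred <- as.numeric(rel %*% cells) / sum(cells)
  tibble::tibble(genus = rownames(m), prediction = pred)
}

#' Competitiveness prediction from final-cycle Elo ratings
#'
#' Ratings are first shifted by the minimum (`Elo' = Elo - min(Elo)`), then
#' normalised to sum to 1; the normalised weights are the predicted relative
#' abundances, so the minimum-rated genus is always predicted at 0. The
#' cell-scale expected abundance (`weight * median cell count`) is reported
#' alongside for completeness, but comparisons with observations are made on
#' the shared relative-abundance scale.
#'
#' @param elo Final-cycle ratings: an `elo_state`, an `elo_trajectory` (its
#'   last rated cycle is used), or a named numeric vector.
#' @param cell_counts Optional per-microcosm cell counts of the final cycle,
#'   used only for the reported cell-scale column.
#' @return A tibble: `genus`, `rating`, `prediction` (sums to 1) and, when
#'   cell counts are given, `expected_cells`.
#' @export
#' @examples
#' predict_competitive(c(gA = 1100, gB = 1000, gC = 900)) # 2/3, 1/3, 0
predict_competitive <- function(elo, cell_counts = NULL) {
  ratings <- if (inherits(elo, "elo_state")) {
    elo$ratings
  } else if (inherits(elo, "elo_trajectory")) {
    last <- max(elo$trajectory$cycle)
    d <- dplyr::filter(elo$trajectory, .data$cycle == last)
    stats::setNames(d$rating, d$genus)
  } else {
    elo
  }
  if (length(ratings) < 2L) stop("need at least 2 rated genera", call. = FALSE)
  shifted <- ratings - min(ratings)
  if (sum(shifted) == 0) {
    stop("degenerate ratings: all equal, weights are all zero", call. = FALSE)
  }
  w <- shifted / sum(shifted)
  out <- tibble::tibble(genus = names(ratings), rating = as.numeric(ratings),
                        prediction = as.numeric(w))
  if (!is.null(cell_counts)) out$expected_cells <- out$prediction * stats::median(cell_counts)
  out
}

# one-sample location test of observed values against mu; chooses a t-test
# when Shapiro-Wilk does not reject normality, a Wilcoxon signed-rank test
# otherwise; exact-match and zero-variance edge cases short-circuit
one_sample_test <- function(obs, mu, shapiro_alpha = 0.05) {
  if (stats::sd(obs) == 0) {
    p <- if (isTRUE(all.equal(unname(obs[1]), unname(mu), tolerance = 1e-12))) 1 else 0
    return(list(p = p, test = "exact"))
  }
  sw <- tryCatch(stats::shapiro.test(obs)$p.value, error = function(e) 0)
  if (sw >= shapiro_alpha) {
    list(p = stats::t.test(obs, mu = mu)$p.value, test = "t")
  } else {
    list(p = suppressWarnings(stats::wilcox.test(obs, mu = mu, correct = TRUE)$p.value),
         test = "wilcoxon")
  }
}

#' Classify genera by which model predicts their post-coalescence abundance
#'
#' Each genus's observed relative abundances across the post-coalescence
#' microcosms are tested against the neutral and the competitiveness
#' prediction as null hypotheses (one-sample t-test when Shapiro-Wilk does
#' not reject normality at `shapiro_alpha`, one-sample Wilcoxon otherwise);
#' p-values are Benjamini-Hochberg adjusted within each model's family.
#' Categories: `excluded` (undetected in every microcosm), `neutral` /
#' `competitive` (that model retained; when both are retained, the one with
#' the higher adjusted p-value), `overperforming` / `underperforming` (both
#' rejected and the observed median above / below both predictions), and
#' `ambiguous` (both rejected, observed median between the predictions).
#'
#' @param observed Abundance table (or count matrix) of the post-coalescence
#'   cycle (>= 3 microcosms).
#' @param neutral_pred Tibble from [predict_neutral()] (or named vector).
#' @param competitive_pred Tibble from [predict_competitive()] (or named
#'   vector). Genera missing from a prediction are predicted at 0 by that
#'   model.
#' @param alpha Significance level on the adjusted p-values (default 0.05).
#' @param shapiro_alpha Normality-test level for the t/Wilcoxon choice
#'   (default 0.05).
#' @return An object of class `coalescence_prediction`: tibble with one row
#'   per genus (`genus`, `pred_neutral`, `pred_competitive`, `obs_mean`,
#'   `obs_median`, `p_neutral`, `p_competitive`, `q_neutral`,
#'   `q_competitive`, `test_neutral`, `test_competitive`, `category`).
#' @export
classify_genera <- function(observed, neutral_pred, competitive_pred,
                            alpha = 0.05, shapiro_alpha = 0.05) {
  m <- if (is.data.frame(observed)) count_matrix(observed) else as.matrix(observed)
  if (ncol(m) < 3L) stop("need >= 3 post-coalescence microcosms", call. = FALSE)
  rel <- sweep(m, 2, pmax(colSums(m), 1), "/")
  as_named <- function(x) {
    if (is.data.frame(x)) stats::setNames(x$prediction, x$genus) else x
  }
  pn <- as_named(neutral_pred)
  pc <- as_named(competitive_pred)
  genera <- rownames(m)
  pn <- ifelse(genera %in% names(pn), pn[genera], 0)
  pc <- ifelse(genera %in% names(pc), pc[genera], 0)
  rows <- purrr::map(seq_along(genera), function(i) {
    obs <- rel[i, ]
    if (all(m[i, ] == 0)) {
      return(tibble::tibble(genus = genera[i], pred_neutral = pn[i],
                            pred_competitive = pc[i], obs_mean = 0, obs_median = 0,
                            p_neutral = NA_real_, p_competitive = NA_real_,
                            test_neutral = "none", test_competitive = "none",
                            excluded = TRUE))
    }
    tn <- one_sample_test(obs, pn[i], shapiro_alpha)
    tc <- one_sample_test(obs, pc[i], shapiro_alpha)
    tibble::tibble(genus = genera[i], pred_neutral = pn[i], pred_competitive = pc[i],
                   obs_mean = mean(obs), obs_median = stats::median(obs),
                   p_neutral = tn$p, p_competitive = tc$p,
                   test_neutral = tn$test, test_competitive = tc$test,
                   excluded = FALSE)
  })
  res <- dplyr::bind_rows(rows)
  res$q_neutral <- stats::p.adjust(res$p_neutral, method = "BH")
  res$q_competitive <- stats::p.adjust(res$p_competitive, method = "BH")
  res$category <- purrr::pmap_chr(
    list(res$excluded, res$q_neutral, res$q_competitive, res$obs_median,
         res$pred_neutral, res$pred_competitive),
    function(excl, qn, qc, med, predn, predc) {
      if (excl) return("excluded")
      keep_n <- qn >= alpha
      keep_c <- qc >= alpha
      if (keep_n && keep_c) return(if (qn >= qc) "neutral" else "competitive")
      if (keep_n) return("neutral")
      if (keep_c) return("competitive")
      if (med > max(predn, predc)) return("overperforming")
      if (med < min(predn, predc)) return("underperforming")
      "ambiguous"
    }
  )
  res$excluded <- NULL
  res <- dplyr::relocate(res, "genus", "pred_neutral", "pred_competitive",
                         "obs_mean", "obs_median", "p_neutral", "p_competitive",
                         "q_neutral", "q_competitive")
  class(res) <- c("coalescence_prediction", class(res))
  attr(res, "alpha") <- alpha
  res
}

#' Glance at a coalescence classification
#' @param x A `coalescence_prediction`.
#' @param ... Unused.
#' @return One-row tibble with genus counts per category.
#' @export
glance.coalescence_prediction <- function(x, ...) {
  lv <- c("neutral", "competitive", "overperforming", "underperforming",
          "excluded", "ambiguous")
  counts <- table(factor(x$category, levels = lv))
  out <- tibble::as_tibble(as.list(counts))
  out$n_genera <- nrow(x)
  out
}

#' Per-category genus counts and read proportions
#'
#' Summarises a classification: how many genera fall in each category and
#' what mean +- SD share of the reads they hold across the post-coalescence
#' microcosms (shares per category sum to <= 1 within each microcosm).
#'
#' @param prediction_result A `coalescence_prediction`.
#' @param observed The post-coalescence abundance table the classification was
#'   made on.
#' @return A tibble: `category`, `n_genera`, `mean_read_share`,
#'   `sd_read_share`.
#' @export
summarize_outcomes <- function(prediction_result, observed) {
  stopifnot(inherits(prediction_result, "coalescence_prediction"))
  m <- if (is.data.frame(observed)) count_matrix(observed) else as.matrix(observed)
  rel <- sweep(m, 2, pmax(colSums(m), 1), "/")
  lv <- c("neutral", "competitive", "overperforming", "underperforming",
          "excluded", "ambiguous")
  cat_of <- stats::setNames(prediction_result$category, prediction_result$genus)
  purrr::map_dfr(lv, function(cc) {
    genera <- names(cat_of)[cat_of == cc]
    share <- if (length(genera) == 0) rep(0, ncol(rel)) else
      colSums(rel[rownames(rel) %in% genera, , drop = FALSE])
    tibble::tibble(category = cc, n_genera = length(genera),
                   mean_read_share = mean(share), sd_read_share = stats::sd(share))
  })
}
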