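#' Fit the exponential-decay score function
#'
#' The multiplayer Elo update needs a score for each abundance rank within a
#' microcosm. Following the observation that within-microcosm rank-abundance
#' curves decay approximately exponentially, the score function
#' `So(rank) = a * exp(-b * rank)` is fitted by nonlinear least squares
#' (Levenberg-Marquardt, [minpack.lm::nlsLM()]) to the pooled
#' (rank, relative abundance) data of all supplied tables. Because the score
#' function maps a rank to its expected score, the default fits the mean
#' relative abundance per rank (`aggregate = "mean"`); `aggregate = "points"`
#' fits every pooled point instead (same curve; its R^2 then also absorbs the
#' between-microcosm scatter around the mean profile).
#'
#' @param tables A list of abundance tables (or a single table); typically all
#'   rated cycles of one experiment.
#' @param min_count Genera with counts below this are excluded from the fit
#'   (default 1, i.e. only present genera enter).
#' @param aggregate `"mean"` (default) or `"points"`; see Details.
#' @return An object of class `score_function`: list with `a`, `b`,
#'   `r_squared`, `n_points`.
#' @export
fit_score_function <- function(tables, min_count = 1, aggregate = c("mean", "points")) {
  aggregate <- match.arg(aggregate)
  if (is.data.frame(tables)) tables <- list(tables)
  if (length(tables) < 1L) stop("need at least one table", call. = FALSE)
  pts <- purrr::map_dfr(tables, function(tab) {
    m <- count_matrix(tab)
    purrr::map_dfr(seq_len(ncol(m)), function(j) {
      col <- m[, j]
      col <- col[col >= min_count]
      if (length(col) == 0L) return(NULL)
      tibble::tibble(rank = rank(-col, ties.method = "average"),
                     rel_abundance = col / sum(col))
    })
  })
  if (aggregate == "mean") {
    pts <- pts |>
      dplyr::group_by(rank = round(.data$rank)) |>
      dplyr::summarise(rel_abundance = mean(.data$rel_abundance), .groups = "drop")
  }
  if (length(unique(pts$rank)) < 2L) {
    stop("fit failure: fewer than 2 distinct ranks observed", call. = FALSE)
  }
  if (stats::sd(pts$rel_abundance) == 0) {
    stop("fit failure: all abundances equal; consider uniform scores", call. = FALSE)
  }
  # log-linear start values
  lf <- stats::lm(log(rel_abundance) ~ rank, data = pts)
  start <- list(a = exp(stats::coef(lf)[[1]]), b = max(-stats::coef(lf)[[2]], 1e-6))
  fit <- minpack.lm::nlsLM(rel_abundance ~ a * exp(-b * rank), data = pts,
                           start = start, control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(fit)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((pts$rel_abundance - mean(pts$rel_abundance))^2)
  structure(list(a = unname(co[["a"]]), b = unname(co[["b"]]),
                 r_squared = 1 - ss_res / ss_tot, n_points = nrow(pts)),
            class = "score_function")
}

#' @export
print.score_function <- function(x, ...) {
  cat(sprintf("<score_function> So(rank) = %.4f * exp(-%.4f * rank); R^2 = %.3f (%d points)\n",
              x$a, x$b, x$r_squared, x$n_points))
  invisible(x)
}

#' Evaluate a score function at given ranks
#'
#' @param object A `score_function`.
#' @param rank Numeric ranks (1 = most abundant).
#' @param ... Unused.
#' @return `a * exp(-b * rank)`.
#' @export
predict.score_function <- function(object, rank, ...) {
  object$a * exp(-object$b * rank)
}

#' Glance at a score-function fit
#' @param x A `score_function`.
#' @param ... Unused.
#' @return One-row tibble with `a`, `b`, `r_squared`, `n_points`.
#' @export
glance.score_function <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, r_squared = x$r_squared, n_points = x$n_points)
}

#' Normalised match scores for a set of participants
#'
#' Participants are ranked by decreasing abundance; each rank's raw score
#' comes from the score function; abundance ties share the mean of their
#' ranks' scores; scores are rescaled to sum to 1 over the participants.
#'
#' @param score_function A `score_function`.
#' @param abundances Named non-negative abundances of the participants.
#' @return Named numeric scores summing to 1.
#' @export
match_scores <- function(score_function, abundances) {
  if (length(abundances) < 1L) stop("no participants", call. = FALSE)
  r_first <- rank(-abundances, ties.method = "first")
  raw <- predict(score_function, r_first)
  # ties share the mean score of the ranks they occupy
  raw <- stats::ave(raw, factor(-abundances), FUN = mean)
  out <- raw / sum(raw)
  names(out) <- names(abundances)
  out
}

#' Initialise a multiplayer Elo state
#'
#' @param genera Optional character vector of genera to rate from the start.
#' @param initial Initial rating for every (newly seen) genus (default 1000).
#' @param K Update budget per match (default 32).
#' @param D Logistic scale of the rating-based expected score (default 400).
#' @param mode `"rating"` (default) for the logistic pairwise expected score,
#'   or `"uniform"` for `Se = 1/N` (every participant expected to do equally
#'   well).
#' @return An object of class `elo_state`.
#' @export
elo_state <- function(genera = character(), initial = 1000, K = 32, D = 400,
                      mode = c("rating", "uniform")) {
  mode <- match.arg(mode)
  if (K <= 0) stop("K must be > 0", call. = FALSE)
  ratings <- stats::setNames(rep(initial, length(genera)), genera)
  structure(list(ratings = ratings, initial = initial, K = K, D = D, mode = mode),
            class = "elo_state")
}

#' @export
print.elo_state <- function(x, ...) {
  cat("<elo_state>", length(x$ratings), "rated genera; K =", x$K,
      "D =", x$D, "mode =", x$mode, "\n")
  invisible(x)
}

#' Tidy an Elo state
#' @param x An `elo_state`.
#' @param ... Unused.
#' @return Tibble with `genus`, `rating`, sorted by decreasing rating.
#' @export
tidy.elo_state <- function(x, ...) {
  tibble::tibble(genus = names(x$ratings), rating = as.numeric(x$ratings)) |>
    dplyr::arrange(dplyr::desc(.data$rating))
}

# expected scores: rating-based logistic pairwise form, normalised over pairs,
# or uniform 1/N
expected_scores <- function(ratings, D, mode) {
  n <- length(ratings)
  if (mode == "uniform") return(rep(1 / n, n))
  M <- outer(ratings, ratings, "-") / D # M[i, j] = R_i - R_j
  E <- 1 / (1 + 10^(-M)) # E[i, j] = P(i beats j)
  (rowSums(E) - 0.5) / (n * (n - 1) / 2)
}

#' One multiplayer Elo match update
#'
#' Updates the ratings of the participating genera of one microcosm:
#' `rating' = rating + K * (N - 1) * (So - Se)`, with the observed score `So`
#' from the rank-based score function (normalised to sum to 1 over
#' participants) and the expected score `Se` either rating-based (default) or
#' uniform `1/N`. Non-participants are unchanged; genera never seen before
#' enter at the initial rating.
#'
#' @param state An `elo_state`.
#' @param abundances Named abundances of the participating genera (>= 2).
#' @param score_function A `score_function` (or precomputed normalised scores
#'   passed via `scores`).
#' @param scores Optional named normalised scores overriding the score
#'   function (must sum to 1).
#' @return The updated `elo_state`.
#' @export
match_update <- function(state, abundances, score_function = NULL, scores = NULL) {
  stopifnot(inherits(state, "elo_state"))
  if (is.null(scores)) {
    if (is.null(score_function)) stop("supply `score_function` or `scores`", call. = FALSE)
    scores <- match_scores(score_function, abundances)
  }
  genera <- names(scores)
  if (is.null(genera) || anyDuplicated(genera)) stop("participants must be uniquely named", call. = FALSE)
  n <- length(genera)
  if (n < 2L) {
    warning("single participant: match is a no-op")
    return(state)
  }
  new <- setdiff(genera, names(state$ratings))
  if (length(new) > 0) {
    state$ratings <- c(state$ratings, stats::setNames(rep(state$initial, length(new)), new))
  }
  r <- state$ratings[genera]
  se <- expected_scores(r, state$D, state$mode)
  state$ratings[genera] <- r + state$K * (n - 1) * (as.numeric(scores) - se)
  state
}

# internal: run one full pass over the microcosms of a cycle in the given
# order, reusing precomputed per-microcosm scores
run_pass <- function(ratings, per_match, order, K, D, mode, initial) {
  for (k in order) {
    sc <- per_match[[k]]
    n <- length(sc)
    if (n < 2L) next
    genera <- names(sc)
    miss <- setdiff(genera, names(ratings))
    if (length(miss) > 0) ratings <- c(ratings, stats::setNames(rep(initial, length(miss)), miss))
    r <- ratings[genera]
    se <- expected_scores(r, D, mode)
    ratings[genera] <- r + K * (n - 1) * (sc - se)
  }
  ratings
}

#' Permutation-averaged Elo ratings for one cycle
#'
#' Because sequential Elo updates depend on the order in which microcosms are
#' visited, the microcosm order is randomised `n_perm` times; the per-genus
#' mean final rating (and its SD across permutations) is reported. Genera are
#' rated if their relative abundance exceeds `abundance_floor` in at least one
#' microcosm (or if they are listed in `rated_genera`); within a microcosm the
#' participants are the rated genera present with count > 0.
#'
#' @param state Starting `elo_state` (carried over from the previous cycle).
#' @param table Abundance table of the cycle.
#' @param score_function A fitted `score_function`.
#' @param n_perm Number of microcosm-order permutations (default 1000).
#' @param abundance_floor Relative-abundance inclusion floor (default 0.001,
#'   i.e. >0.1% in at least one microcosm).
#' @param rated_genera Optional explicit rated set (overrides the floor).
#' @param seed Optional seed for the permutations.
#' @return A list with `state` (the `elo_state` holding permutation-mean
#'   ratings) and `summary` (tibble: genus, rating, sd).
#' @export
rate_cycle <- function(state, table, score_function, n_perm = 1000,
                       abundance_floor = 0.001, rated_genera = NULL, seed = NULL) {
  stopifnot(inherits(state, "elo_state"))
  if (!is.numeric(n_perm) || n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)
  m <- count_matrix(table)
  if (is.null(rated_genera)) {
    rel <- sweep(m, 2, pmax(colSums(m), 1), "/")
    rated_genera <- rownames(m)[apply(rel > abundance_floor, 1, any)]
  }
  if (length(rated_genera) < 2L) stop("fewer than 2 rated genera above the floor", call. = FALSE)
  per_match <- lapply(seq_len(ncol(m)), function(j) {
    col <- m[rownames(m) %in% rated_genera, j]
    col <- col[col > 0]
    if (length(col) < 2L) return(numeric(0))
    match_scores(score_function, col)
  })
  base <- state$ratings
  miss <- setdiff(rated_genera, names(base))
  if (length(miss) > 0) base <- c(base, stats::setNames(rep(state$initial, length(miss)), miss))
  run <- function() {
    acc <- matrix(NA_real_, nrow = n_perm, ncol = length(base),
                  dimnames = list(NULL, names(base)))
    for (p in seq_len(n_perm)) {
      ord <- sample.int(ncol(m))
      acc[p, ] <- run_pass(base, per_match, ord, state$K, state$D, state$mode,
                           state$initial)[names(base)]
    }
    acc
  }
  acc <- if (!is.null(seed)) withr::with_seed(seed, run()) else run()
  means <- colMeans(acc)
  sds <- apply(acc, 2, stats::sd)
  if (n_perm == 1L) sds[] <- 0
  new_state <- state
  new_state$ratings <- means
  list(state = new_state,
       summary = tibble::tibble(genus = names(means), rating = as.numeric(means),
                                sd = as.numeric(sds)) |>
         dplyr::filter(.data$genus %in% rated_genera) |>
         dplyr::arrange(dplyr::desc(.data$rating)))
}

#' Elo trajectory across the rated cycles of an experiment
#'
#' Applies [rate_cycle()] to each requested cycle in order; the
#' permutation-mean ratings of cycle c seed cycle c+1 (set
#' `reset_each_cycle = TRUE` to start every cycle from scratch). The >0.1%
#' inclusion floor is evaluated jointly across all rated cycles: a genus
#' exceeding the floor anywhere is rated everywhere it occurs (set
#' `joint_floor = FALSE` for a per-cycle floor).
#'
#' @param experiment A `melo_experiment` or a named list of abundance tables
#'   (`C0`, `C1`, ...).
#' @param cycles Integer cycle ids to rate (default `c(0, 1, 4, 6)`).
#' @param score_function Optional prefitted `score_function`; by default it is
#'   fitted to the requested cycles' tables.
#' @param n_perm Microcosm-order permutations per cycle (default 1000).
#' @param abundance_floor Relative-abundance floor (default 0.001).
#' @param joint_floor Apply the floor jointly across cycles (default TRUE).
#' @param reset_each_cycle Restart ratings at `initial` each cycle
#'   (default FALSE).
#' @param K,D,mode,initial Passed to [elo_state()].
#' @param seed Optional seed.
#' @return An object of class `elo_trajectory`: list with `trajectory`
#'   (tibble: genus, cycle, rating, sd), `final_state`, `score_function`,
#'   `n_perm`, `cycles`.
#' @export
rate_experiment <- function(experiment, cycles = c(0, 1, 4, 6),
                            score_function = NULL, n_perm = 1000,
                            abundance_floor = 0.001, joint_floor = TRUE,
                            reset_each_cycle = FALSE, K = 32, D = 400,
                            mode = c("rating", "uniform"), initial = 1000,
                            seed = NULL) {
  mode <- match.arg(mode)
  tables <- if (inherits(experiment, "melo_experiment")) experiment$tables else experiment
  ids <- paste0("C", cycles)
  missing_ids <- setdiff(ids, names(tables))
  if (length(missing_ids) > 0) {
    stop("cycle(s) not present in the experiment: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  tables <- tables[ids]
  if (is.null(score_function)) score_function <- fit_score_function(tables)
  rated_joint <- NULL
  if (joint_floor) {
    rated_joint <- unique(unlist(lapply(tables, function(tab) {
      m <- count_matrix(tab)
      rel <- sweep(m, 2, pmax(colSums(m), 1), "/")
      rownames(m)[apply(rel > abundance_floor, 1, any)]
    })))
  }
  run <- function() {
    state <- elo_state(K = K, D = D, mode = mode, initial = initial)
    traj <- vector("list", length(ids))
    for (i in seq_along(ids)) {
      if (reset_each_cycle) state <- elo_state(K = K, D = D, mode = mode, initial = initial)
      rated <- if (joint_floor) {
        m <- count_matrix(tables[[i]])
        intersect(rated_joint, rownames(m)[rowSums(m) > 0])
      } else NULL
      res <- rate_cycle(state, tables[[i]], score_function, n_perm = n_perm,
                        abundance_floor = abundance_floor, rated_genera = rated)
      state <- res$state
      traj[[i]] <- dplyr::mutate(res$summary, cycle = cycles[i], .before = 1)
    }
    list(state = state, traj = dplyr::bind_rows(traj))
  }
  out <- if (!is.null(seed)) withr::with_seed(seed, run()) else run()
  structure(list(trajectory = dplyr::relocate(out$traj, "genus"),
                 final_state = out$state, score_function = score_function,
                 n_perm = n_perm, cycles = cycles),
            class = "elo_trajectory")
}

#' @export
print.elo_trajectory <- function(x, ...) {
  cat("<elo_trajectory>", length(unique(x$trajectory$genus)), "genera over cycles",
      paste(x$cycles, collapse = ", "), sprintf("(n_perm = %d)\n", x$n_perm))
  invisible(x)
}

#' Tidy an Elo trajectory
#' @param x An `elo_trajectory`.
#' @param ... Unused.
#' @return The trajectory tibble (genus, cycle, rating, sd).
#' @export
tidy.elo_trajectory <- function(x, ...) x$trajectory

#' Per-genus competitiveness trends
#'
#' Spearman rank correlation of a genus's permutation-mean rating against
#' cycle number, for genera rated in at least `min_cycles` cycles. With only
#' four rated cycles the exact permutation p-value can never reach 0.05, so
#' the t-approximation is used by default (`exact = FALSE`); set
#' `exact = TRUE` for the exact test.
#'
#' @param trajectory An `elo_trajectory` (or its tidied tibble).
#' @param alpha Significance level for the direction call (default 0.05).
#' @param min_cycles Minimum rated cycles per genus (default 3).
#' @param exact Passed to [stats::cor.test()] (default FALSE).
#' @param adjust Apply Benjamini-Hochberg across genera and base the
#'   direction on the adjusted q-value (default FALSE, matching per-genus
#'   inference).
#' @return A tibble: genus, n_cycles, rho, p_value (and q_value when
#'   `adjust`), direction in `increasing`/`decreasing`/`none`.
#' @export
elo_trend <- function(trajectory, alpha = 0.05, min_cycles = 3, exact = FALSE,
                      adjust = FALSE) {
  tr <- if (inherits(trajectory, "elo_trajectory")) trajectory$trajectory else trajectory
  res <- tr |>
    dplyr::group_by(.data$genus) |>
    dplyr::group_modify(function(d, key) {
      empty <- tibble::tibble(n_cycles = integer(0), rho = numeric(0),
                              p_value = numeric(0))
      if (nrow(d) < min_cycles) return(empty)
      if (stats::sd(d$rating) == 0) {
        return(tibble::tibble(n_cycles = nrow(d), rho = NA_real_, p_value = NA_real_))
      }
      ct <- suppressWarnings(stats::cor.test(d$rating, d$cycle, method = "spearman",
                                             exact = exact))
      tibble::tibble(n_cycles = nrow(d), rho = unname(ct$estimate), p_value = ct$p.value)
    }) |>
    dplyr::ungroup()
  if (nrow(res) == 0L) stop("no genus rated in >= ", min_cycles, " cycles", call. = FALSE)
  pcol <- "p_value"
  if (adjust) {
    res$q_value <- stats::p.adjust(res$p_value, method = "BH")
    pcol <- "q_value"
  }
  res$direction <- dplyr::case_when(
    is.na(res$rho) | is.na(res[[pcol]]) ~ "none",
    res[[pcol]] < alpha & res$rho > 0 ~ "increasing",
    res[[pcol]] < alpha & res$rho < 0 ~ "decreasing",
    TRUE ~ "none"
  )
  res
}
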