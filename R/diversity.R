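#' Rarefy an abundance table to a common depth
#'
#' Subsamples every microcosm column without replacement to exactly `depth`
#' reads (via [vegan::rrarefy()]). Columns whose total is below `depth` are
#' dropped with a warning, mirroring the usual practice of rarefying to the
#' read count of the lowest retained sample.
#'
#' @param table An abundance table of read counts.
#' @param depth Target depth (> 0). Default: the minimum column sum.
#' @param seed Optional seed for the subsampling.
#' @return A rarefied abundance table; dropped microcosm ids are recorded in
#'   attribute `"dropped"`.
#' @export
#' @examples
#' tab <- abundance_table(matrix(c(10, 0, 0, 4, 4, 2), 3, 2), cycle = 0)
#' colSums(count_matrix(rarefy(tab, depth = 5, seed = 1)))
rarefy <- function(table, depth = NULL, seed = NULL) {
  m <- count_matrix(table)
  if (is.null(depth)) depth <- min(colSums(m))
  if (!is.numeric(depth) || length(depth) != 1L || depth <= 0) {
    stop("`depth` must be a single positive number", call. = FALSE)
  }
  depth <- round(depth)
  keep <- colSums(m) >= depth
  if (!any(keep)) stop("no microcosm reaches depth ", depth, call. = FALSE)
  if (any(!keep)) {
    warning("dropping microcosm(s) below depth ", depth, ": ",
            paste(colnames(m)[!keep], collapse = ", "))
  }
  sub <- m[, keep, drop = FALSE]
  # vegan warns whenever the smallest nonzero count exceeds 1; that is the
  # normal situation for read tables, so that specific warning is muffled
  draw <- function() {
    withCallingHandlers(
      t(vegan::rrarefy(t(sub), sample = depth)),
      warning = function(w) {
        if (grepl("smallest count", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  }
  out <- if (!is.null(seed)) withr::with_seed(seed, draw()) else draw()
  res <- abundance_table(out, genus = rownames(m))
  attr(res, "cycle") <- attr(table, "cycle")
  attr(res, "dropped") <- colnames(m)[!keep]
  res
}

#' Alpha and gamma diversity of a rarefied table
#'
#' Richness is the number of genera with count > 0 per microcosm; Pielou's
#' evenness J is Shannon H (natural log) divided by ln(richness), undefined
#' (NA) when richness <= 1; gamma richness is the number of genera detected in
#' at least one microcosm.
#'
#' @param table A (rarefied) abundance table.
#' @return A tibble with one row per microcosm (`microcosm`, `richness`,
#'   `evenness`) and the regional richness in attribute `"gamma"` and column
#'   `gamma` (recycled).
#' @export
alpha_gamma <- function(table) {
  m <- count_matrix(table)
  rich <- colSums(m > 0)
  H <- vegan::diversity(t(m), index = "shannon")
  J <- ifelse(rich > 1, H / log(rich), NA_real_)
  gamma <- sum(rowSums(m) > 0)
  res <- tibble::tibble(microcosm = colnames(m), richness = as.integer(rich),
                        evenness = as.numeric(J), gamma = as.integer(gamma))
  attr(res, "gamma") <- as.integer(gamma)
  res
}

#' Bray-Curtis dissimilarity between two count vectors
#'
#' `1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))`, computed through
#' [vegan::vegdist()].
#'
#' @param x,y Non-negative numeric vectors of equal length, not both all-zero.
#' @return A dissimilarity in `[0, 1]`.
#' @export
#' @examples
#' bray_curtis(c(6, 2, 0), c(2, 2, 4)) # 0.5
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative", call. = FALSE)
  if (sum(x) == 0 && sum(y) == 0) stop("undefined: both vectors are all-zero", call. = FALSE)
  as.numeric(vegan::vegdist(rbind(x, y), method = "bray"))
}

# Draw one null assemblage: `rich` taxa picked without replacement with
# probability proportional to regional occupancy, one individual each, then
# the remaining individuals filled in multinomially with probability
# proportional to regional relative abundance of the picked taxa.
null_assemblage <- function(rich, total, occupancy, regional) {
  n_tax <- length(occupancy)
  picked <- sample.int(n_tax, size = rich, replace = FALSE, prob = occupancy)
  counts <- numeric(n_tax)
  counts[picked] <- 1
  extra <- total - rich
  if (extra > 0) {
    counts[picked] <- counts[picked] +
      as.numeric(stats::rmultinom(1, size = extra, prob = regional[picked]))
  }
  counts
}

#' Modified Raup-Crick beta diversity with Bray-Curtis
#'
#' For every microcosm pair the observed Bray-Curtis dissimilarity is compared
#' with a null distribution in which taxa are randomly reassigned among
#' communities while preserving each community's richness and total count:
#' taxa are drawn weighted by their regional occupancy (number of microcosms
#' occupied) and individuals are filled in proportional to regional relative
#' abundance (the abundance-weighted null commonly used with this index).
#' \deqn{\beta_{RC} = 2\,\frac{\#(BC_{null} < BC_{obs}) + 0.5\,\#(BC_{null} = BC_{obs})}{n_{null}} - 1}
#' Values below -0.95 flag pairs more similar than chance, above +0.95 less
#' similar than chance.
#'
#' Per null replicate one null assemblage is built per microcosm and all
#' pairwise Bray-Curtis values of that replicate enter the pair-specific null
#' distributions; the marginal null per pair is identical to drawing each
#' pair independently.
#'
#' @param table A rarefied abundance table (>= 2 microcosms with reads).
#' @param n_null Number of null replicates (>= 100; default 1000).
#' @param seed Optional seed.
#' @return An object of class `raup_crick`: list with `beta_rc` (symmetric
#'   matrix, NA diagonal), `n_null`, and `seed`.
#' @export
raup_crick_matrix <- function(table, n_null = 1000, seed = NULL) {
  if (!is.numeric(n_null) || n_null < 100) stop("`n_null` must be >= 100", call. = FALSE)
  m <- count_matrix(table)
  empty <- colSums(m) == 0
  if (any(empty)) {
    warning("excluding zero-total microcosm(s): ", paste(colnames(m)[empty], collapse = ", "))
    m <- m[, !empty, drop = FALSE]
  }
  if (ncol(m) < 2L) stop("need at least 2 non-empty microcosms", call. = FALSE)
  nm <- ncol(m)
  occupancy <- rowSums(m > 0)
  regional <- rowSums(m) / sum(m)
  rich <- colSums(m > 0)
  totals <- colSums(m)
  obs <- as.matrix(vegan::vegdist(t(m), method = "bray"))
  run <- function() {
    lower <- matrix(0, nm, nm)
    ties <- matrix(0, nm, nm)
    for (b in seq_len(n_null)) {
      nulls <- vapply(seq_len(nm), function(j) {
        null_assemblage(rich[j], totals[j], occupancy, regional)
      }, numeric(nrow(m)))
      bc <- as.matrix(vegan::vegdist(t(nulls), method = "bray"))
      lower <- lower + (bc < obs - 1e-12)
      ties <- ties + (abs(bc - obs) <= 1e-12)
    }
    2 * (lower + 0.5 * ties) / n_null - 1
  }
  beta <- if (!is.null(seed)) withr::with_seed(seed, run()) else run()
  dimnames(beta) <- dimnames(obs)
  diag(beta) <- NA_real_
  structure(list(beta_rc = beta, n_null = n_null, seed = seed,
                 cycle = attr(table, "cycle")),
            class = "raup_crick")
}

#' @export
print.raup_crick <- function(x, ...) {
  v <- x$beta_rc[upper.tri(x$beta_rc)]
  cat("<raup_crick>", ncol(x$beta_rc), "microcosms,", length(v), "pairs;",
      "median beta_RC", sprintf("%.3f", stats::median(v)), "\n")
  invisible(x)
}

#' Tidy a Raup-Crick result into one row per pair
#'
#' @param x A `raup_crick` object.
#' @param ... Unused.
#' @return A tibble with columns `microcosm_1`, `microcosm_2`, `beta_rc`.
#' @export
tidy.raup_crick <- function(x, ...) {
  b <- x$beta_rc
  idx <- which(upper.tri(b), arr.ind = TRUE)
  tibble::tibble(microcosm_1 = rownames(b)[idx[, 1]],
                 microcosm_2 = colnames(b)[idx[, 2]],
                 beta_rc = b[idx])
}

#' Classify beta_RC values into the three assembly bins
#'
#' Fractions of unordered pairs that are more similar than chance
#' (`beta_rc < -threshold`), indistinguishable from stochastic assembly
#' (`|beta_rc| <= threshold`), or less similar than chance
#' (`beta_rc > threshold`). Boundary values fall in the middle bin (strict
#' inequalities on the outer bins).
#'
#' @param result A `raup_crick` object (or a numeric vector of beta_RC values).
#' @param threshold Bin threshold (default 0.95).
#' @return A tibble with columns `bin` (`similar`, `stochastic`,
#'   `dissimilar`), `n_pairs`, `fraction`; fractions sum to 1.
#' @export
classify_beta <- function(result, threshold = 0.95) {
  v <- if (inherits(result, "raup_crick")) {
    result$beta_rc[upper.tri(result$beta_rc)]
  } else {
    as.numeric(result)
  }
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("no beta_RC pairs to classify", call. = FALSE)
  bins <- c(similar = sum(v < -threshold),
            stochastic = sum(abs(v) <= threshold),
            dissimilar = sum(v > threshold))
  tibble::tibble(bin = factor(names(bins), levels = names(bins)),
                 n_pairs = as.integer(bins),
                 fraction = as.numeric(bins) / length(v))
}

#' Assign community types from the dominant genus
#'
#' A community type is defined by a genus that has the highest read
#' proportion in at least `min_microcosms` microcosms of the given (final)
#' cycle; microcosms whose top genus dominates fewer microcosms are labelled
#' `"unique"`. Ties for the top genus are broken lexicographically and
#' reported.
#'
#' @param table A single-cycle abundance table.
#' @param min_microcosms Minimum number of microcosms a genus must top to
#'   found a type (default 3).
#' @return A tibble with one row per microcosm: `microcosm`, `top_genus`,
#'   `type`; the type-founding genera are in attribute `"types"` and any tie
#'   break in attribute `"ties"`.
#' @export
assign_community_types <- function(table, min_microcosms = 3) {
  m <- count_matrix(table)
  ord <- order(rownames(m)) # lexicographic tie-break via ordered scan
  top <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[ord, j]
    rownames(m)[ord][which.max(col)]
  }, character(1))
  ties <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    sum(col == max(col)) > 1L
  }, logical(1))
  if (any(ties)) {
    message("top-genus tie(s) broken lexicographically in: ",
            paste(colnames(m)[ties], collapse = ", "))
  }
  tally <- table(top)
  types <- sort(names(tally)[tally >= min_microcosms])
  res <- tibble::tibble(microcosm = colnames(m), top_genus = top,
                        type = ifelse(top %in% types, top, "unique"))
  attr(res, "types") <- types
  attr(res, "ties") <- colnames(m)[ties]
  res
}

#' Carbon use efficiency
#'
#' CUE is the ratio of biomass carbon produced to substrate carbon consumed
#' over a growth cycle.
#'
#' @param biomass_c Biomass-C produced (ug C), non-negative.
#' @param consumed_c Substrate-C consumed (ug C); values <= 0 give NA with a
#'   warning.
#' @return Numeric vector of CUE values.
#' @export
#' @examples
#' carbon_use_efficiency(50, 100) # 0.5
carbon_use_efficiency <- function(biomass_c, consumed_c) {
  if (any(biomass_c < 0, na.rm = TRUE)) stop("biomass_c must be non-negative", call. = FALSE)
  bad <- !is.na(consumed_c) & consumed_c <= 0
  if (any(bad)) warning("CUE undefined where consumed_c <= 0; returning NA")
  out <- ifelse(bad, NA_real_, biomass_c / consumed_c)
  as.numeric(out)
}
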