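# Population-vector odor-separation statistics and the linear-subtraction
# characterization of light effects.

#' Euclidean distance between two population vectors
#'
#' d(p, q) = sqrt((p - q) . (p - q)). When both vectors are named the cell
#' orderings must match.
#'
#' @param p,q numeric vectors of matched per-cell responses.
#' @return nonnegative scalar distance.
#' @examples
#' euclideanDistance(c(1, 2, 2), c(0, 0, 1))  # sqrt(6)
#' @export
euclideanDistance <- function(p, q) {
  if (length(p) != length(q))
    stop("pairing error: vectors differ in length")
  if (!is.null(names(p)) && !is.null(names(q)) &&
      !identical(names(p), names(q)))
    stop("pairing error: cell orderings differ")
  sqrt(sum((p - q)^2))
}

# split trial indices into two halves: odd/even ("half") or a random
# equal split ("random")
.splitTrials <- function(trialIds, strategy, seed) {
  ord <- sort(unique(trialIds))
  if (strategy == "half") {
    list(a = ord[seq_along(ord) %% 2 == 1], b = ord[seq_along(ord) %% 2 == 0])
  } else {
    set.seed(seed)
    sh <- sample(ord)
    h <- length(ord) %/% 2
    list(a = sort(sh[seq_len(h)]), b = sort(sh[(h + 1):length(ord)]))
  }
}

#' Build paired population vectors per session
#'
#' Constructs the vector pairs entering the Euclidean-distance analysis
#' from a long table of per-trial responses. In the "between" design the
#' pair is (mean response to odor 1, mean response to odor 2) over the
#' cells responsive to both odors; in the "within" design the same odor's
#' trials are split into two halves, averaged separately, over the cells
#' responsive to that odor. Sessions (or session-odor combinations) with
#' fewer than \code{minCells} qualifying cells are excluded with the
#' reason recorded.
#'
#' @param responses data.frame with columns \code{session}, \code{cell},
#'   \code{odor}, \code{trial}, \code{value} (per-trial response, e.g. a
#'   z-scored window difference) and \code{responsive} (logical, the
#'   cell-odor responsiveness at the alpha = 0.05 paired-test rule).
#' @param design "within" (same odor, split trials) or "between"
#'   (two odors).
#' @param minCells minimum number of qualifying cells (default 5;
#'   sessions with fewer are excluded, the count and reason recorded).
#' @param split trial-split strategy for the within design: "half"
#'   (odd/even, deterministic) or "random".
#' @param seed seed for the random split.
#' @return list of records, one per session (x odor for "within"), each
#'   with \code{session}, \code{odor} (within) , \code{included},
#'   \code{nCells}, \code{reason}, and when included the named vectors
#'   \code{p} and \code{q}.
#' @export
buildPopulationVectors <- function(responses,
                                   design = c("within", "between"),
                                   minCells = 5,
                                   split = c("half", "random"), seed = 0) {
  design <- match.arg(design)
  split <- match.arg(split)
  need <- c("session", "cell", "odor", "trial", "value", "responsive")
  if (!all(need %in% names(responses)))
    stop("responses must have columns: ", paste(need, collapse = ", "))
  out <- list()
  for (s in unique(responses$session)) {
    rs <- responses[responses$session == s, ]
    odors <- sort(unique(rs$odor))
    if (design == "between") {
      if (length(odors) != 2L)
        stop(sprintf("session %s: between design needs exactly 2 odors", s))
      respCells <- lapply(odors, function(o)
        unique(rs$cell[rs$odor == o & rs$responsive]))
      dual <- sort(intersect(respCells[[1]], respCells[[2]]))
      if (length(dual) < minCells) {
        out[[length(out) + 1L]] <- list(
          session = s, included = FALSE, nCells = length(dual),
          reason = sprintf("only %d cells responsive to both odors (min %d)",
                           length(dual), minCells))
        next
      }
      avg <- function(o) vapply(dual, function(cc)
        mean(rs$value[rs$cell == cc & rs$odor == o]), numeric(1))
      p <- avg(odors[1]); q <- avg(odors[2])
      names(p) <- names(q) <- dual
      out[[length(out) + 1L]] <- list(session = s, included = TRUE,
                                      nCells = length(dual), reason = "",
                                      p = p, q = q)
    } else {
      for (o in odors) {
        ro <- rs[rs$odor == o, ]
        cells <- sort(unique(ro$cell[ro$responsive]))
        if (length(cells) < minCells) {
          out[[length(out) + 1L]] <- list(
            session = s, odor = o, included = FALSE, nCells = length(cells),
            reason = sprintf("only %d responsive cells (min %d)",
                             length(cells), minCells))
          next
        }
        halves <- .splitTrials(ro$trial, split, seed)
        avg <- function(tr) vapply(cells, function(cc)
          mean(ro$value[ro$cell == cc & ro$trial %in% tr]), numeric(1))
        p <- avg(halves$a); q <- avg(halves$b)
        names(p) <- names(q) <- cells
        out[[length(out) + 1L]] <- list(session = s, odor = o,
                                        included = TRUE,
                                        nCells = length(cells), reason = "",
                                        p = p, q = q)
      }
    }
  }
  out
}

#' Per-session population distances across conditions
#'
#' Builds population vectors per condition and computes the per-session
#' Euclidean distances, paired across conditions (e.g. odor-only vs
#' odor+light). No statistical verdict is embedded; pass the returned
#' paired distances to [pairedDistanceTest()].
#'
#' @param responses long data.frame as in [buildPopulationVectors()] with
#'   an additional \code{condition} column.
#' @param design "within" or "between".
#' @param conditions character vector of the two condition labels to pair.
#' @param ... passed to [buildPopulationVectors()].
#' @return data.frame with one row per session (x odor for within):
#'   \code{session}, \code{odorId} (within design), one distance column
#'   per condition, \code{nCells}; sessions not qualifying under either
#'   condition are dropped with a message.
#' @export
distanceAnalysis <- function(responses, design = c("within", "between"),
                             conditions = c("odor", "odor+light"), ...) {
  design <- match.arg(design)
  if (length(conditions) != 2L) stop("need exactly two conditions")
  recs <- lapply(conditions, function(cond) buildPopulationVectors(
    responses[responses$condition == cond, , drop = FALSE],
    design = design, ...))
  keyOf <- function(r) paste(r$session, if (!is.null(r$odor)) r$odor else "",
                             sep = "|")
  k1 <- vapply(recs[[1]], keyOf, character(1))
  k2 <- vapply(recs[[2]], keyOf, character(1))
  common <- intersect(k1, k2)
  rows <- list()
  for (key in common) {
    r1 <- recs[[1]][[match(key, k1)]]
    r2 <- recs[[2]][[match(key, k2)]]
    if (!r1$included || !r2$included) {
      message(sprintf("session %s dropped: %s", key,
                      paste(c(r1$reason, r2$reason), collapse = "; ")))
      next
    }
    # pair on the cells qualifying under both conditions
    cells <- intersect(names(r1$p), names(r2$p))
    if (length(cells) < 1) next
    rows[[length(rows) + 1L]] <- data.frame(
      session = r1$session,
      odorId = if (!is.null(r1$odor)) r1$odor else NA,
      d1 = euclideanDistance(r1$p[cells], r1$q[cells]),
      d2 = euclideanDistance(r2$p[cells], r2$q[cells]),
      nCells = length(cells))
  }
  if (!length(rows)) {
    message("no session qualifies under both conditions")
    return(data.frame(session = character(), odorId = character(),
                      d1 = numeric(), d2 = numeric(), nCells = integer()))
  }
  out <- do.call(rbind, rows)
  names(out)[names(out) == "d1"] <- conditions[1]
  names(out)[names(out) == "d2"] <- conditions[2]
  out
}

#' Paired comparison of per-session distances
#'
#' Two-sided paired t-test on the per-session distances of two conditions,
#' as used downstream of [distanceAnalysis()].
#'
#' @param distances data.frame from [distanceAnalysis()].
#' @param conditions the two distance columns to compare.
#' @return htest object from [stats::t.test()].
#' @export
pairedDistanceTest <- function(distances, conditions = c("odor",
                                                         "odor+light")) {
  stats::t.test(distances[[conditions[2]]], distances[[conditions[1]]],
                paired = TRUE)
}

#' Linear-subtraction fit of light effects on odor responses
#'
#' OLS fit of the odor+light response against the matched odor-only
#' response over responsive cell-odor pairs, with 95% confidence
#' intervals, plus the correlation between the light effect
#' (odor+light - odor) and the odor response. Slope 1, negative intercept
#' and no correlation indicate a subtractive light effect; slope < 1 with
#' intercept 0 would indicate a divisive one.
#'
#' @param odorResponses per-pair odor-only response magnitudes (n >= 3).
#' @param odorLightResponses matched odor+light magnitudes.
#' @return A [SubtractionFit-class].
#' @export
linearSubtractionFit <- function(odorResponses, odorLightResponses) {
  if (length(odorResponses) != length(odorLightResponses))
    stop("pairing error: response vectors differ in length")
  n <- length(odorResponses)
  if (n < 3L) stop("need at least 3 matched pairs")
  if (stats::sd(odorResponses) == 0)
    stop("fit error: degenerate (constant) odor responses")
  fit <- stats::lm(odorLightResponses ~ odorResponses)
  ci <- stats::confint(fit, level = 0.95)
  diff <- odorLightResponses - odorResponses
  if (stats::sd(diff) == 0) {
    r <- 0; pr <- 1                      # exact subtraction: no correlation
  } else {
    ct <- stats::cor.test(diff, odorResponses)
    r <- unname(ct$estimate); pr <- ct$p.value
  }
  new("SubtractionFit",
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      slopeCI = unname(ci[2, ]), interceptCI = unname(ci[1, ]),
      diffCor = r, diffCorP = pr, n = as.integer(n))
}
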