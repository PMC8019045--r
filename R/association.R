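# Dyadic simple association indices from scan samples.
#
# The simple association index of a dyad is the fraction of scans containing
# both units among scans containing at least one (the "union" denominator).
# The raw-sum denominator N_AB / (N_A + N_B), the formula some field reports
# print, is available as a sensitivity option; it does not reach 1 for dyads
# that are always together.

#' Units present in a scan
#'
#' Presence in a scan means membership of the focal-centred 50 m aggregation:
#' the focal unit itself plus every recorded associate.
#'
#' @param scan one row of a scan tibble (see [scan_table()]).
#' @return character vector of unit identifiers.
#' @export
unit_presence <- function(scan) {
  unique(c(scan$focal_unit, scan$associates[[1]]))
}

#' Scan-by-unit presence matrix
#'
#' @param scans scan tibble.
#' @param units roster (character); defaults to all units seen in the scans.
#' @param strict error if a scanned unit is missing from the supplied roster.
#' @return logical matrix, rows = scans, columns = units.
#' @export
presence_matrix <- function(scans, units = NULL, strict = FALSE) {
  seen <- unique(c(scans$focal_unit, unlist(scans$associates)))
  if (is.null(units)) {
    units <- sort(seen)
  } else if (strict && length(setdiff(seen, units))) {
    stop("scans mention units absent from the roster: ",
         paste(setdiff(seen, units), collapse = ", "), call. = FALSE)
  }
  m <- matrix(FALSE, nrow(scans), length(units), dimnames = list(NULL, units))
  for (i in seq_len(nrow(scans))) {
    pres <- intersect(unit_presence(scans[i, ]), units)
    m[i, pres] <- TRUE
  }
  m
}

#' Dyad sighting counts
#'
#' Counts, over a set of scans, how often units `a` and `b` were seen
#' together (`n_joint`), alone (`n_a_only`, `n_b_only`), and in total
#' (`n_union`); a scan contributes only if at least one member is present.
#'
#' @param scans scan tibble.
#' @param a,b distinct unit identifiers.
#' @return one-row tibble with `n_joint`, `n_a_only`, `n_b_only`, `n_union`.
#' @export
dyad_counts <- function(scans, a, b) {
  if (identical(a, b)) stop("`a` and `b` must be distinct units", call. = FALSE)
  m <- presence_matrix(scans, units = unique(c(a, b, scans$focal_unit,
                                               unlist(scans$associates))))
  in_a <- m[, a]
  in_b <- m[, b]
  tibble::tibble(
    n_joint = sum(in_a & in_b),
    n_a_only = sum(in_a & !in_b),
    n_b_only = sum(in_b & !in_a),
    n_union = sum(in_a | in_b)
  )
}

#' Simple association index
#'
#' `n_joint / n_union`: 1 when the two units were always in association in
#' the sample, 0 when never. A dyad whose members were never sighted at all
#' (`n_union = 0`) has no defined index and returns `NA`.
#'
#' @param counts a [dyad_counts()] row (or any list with those fields).
#' @param denominator `"union"` (default) or `"sum"` for the raw-sum variant
#'   `n_joint / (n_a + n_b)` where `n_a = n_joint + n_a_only`.
#' @return a value in `[0, 1]`, or `NA` when undefined.
#' @export
simple_ai <- function(counts, denominator = c("union", "sum")) {
  denominator <- match.arg(denominator)
  den <- if (denominator == "union") {
    counts$n_joint + counts$n_a_only + counts$n_b_only
  } else {
    2 * counts$n_joint + counts$n_a_only + counts$n_b_only
  }
  ifelse(den > 0, counts$n_joint / den, NA_real_)
}

#' Association matrix over a roster of units
#'
#' Builds the symmetric unit-by-unit matrix of simple association indices
#' for one period, retaining the dyad counts as provenance. Dyads with
#' `n_union = 0` are flagged undefined: their AI is stored as 0 (so the
#' matrix can feed clustering and network construction directly) and
#' `defined` is `FALSE` (so they can be excluded from CV-type statistics).
#'
#' @param scans scan tibble (already filtered to the period of interest).
#' @param units roster; defaults to all units appearing in the scans.
#' @param period optional length-2 `Date` vector recording the span.
#' @param strict error if scans mention units outside the roster.
#' @inheritParams simple_ai
#' @return an `assoc_matrix` object with elements `units`, `ai` (numeric
#'   matrix), `defined` (logical matrix), `joint`/`n_union` count matrices,
#'   `sightings` (per-unit totals), `n_scans`, and `period`.
#' @export
association_matrix <- function(scans, units = NULL, period = NULL,
                               strict = FALSE, denominator = c("union", "sum")) {
  denominator <- match.arg(denominator)
  m <- presence_matrix(scans, units = units, strict = strict)
  ai_from_presence(m, period = period, denominator = denominator)
}

# core computation, shared with the permutation engines: m is a logical or
# 0/1 matrix scans x units.
ai_from_presence <- function(m, period = NULL, denominator = "union") {
  units <- colnames(m)
  if (length(units) < 2) stop("need at least 2 units", call. = FALSE)
  storage.mode(m) <- "double"
  joint <- crossprod(m)                   # N_AB (diag = N_A)
  n_ind <- diag(joint)
  den <- if (denominator == "union") {
    outer(n_ind, n_ind, "+") - joint      # |A u B|
  } else {
    outer(n_ind, n_ind, "+")              # N_A + N_B
  }
  defined <- den > 0
  ai <- matrix(0, length(units), length(units), dimnames = dimnames(joint))
  ai[defined] <- joint[defined] / den[defined]
  diag(ai) <- NA_real_
  diag(defined) <- FALSE
  structure(
    list(
      units = units, ai = ai, defined = defined, joint = joint,
      n_union = outer(n_ind, n_ind, "+") - joint,
      sightings = stats::setNames(n_ind, units),
      n_scans = nrow(m), period = period, denominator = denominator
    ),
    class = "assoc_matrix"
  )
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat(sprintf("Association matrix: %d units, %d scans", length(x$units), x$n_scans))
  if (!is.null(x$period)) cat(sprintf(", %s to %s", x$period[1], x$period[2]))
  vals <- x$ai[upper.tri(x$ai)][x$defined[upper.tri(x$defined)]]
  cat(sprintf("\nDefined dyads: %d/%d; mean AI %.3f, range %.3f-%.3f\n",
              sum(x$defined[upper.tri(x$defined)]), choose(length(x$units), 2),
              mean(vals), min(vals), max(vals)))
  invisible(x)
}

#' Tidy an association matrix into a long dyad table
#'
#' @param x an `assoc_matrix`.
#' @param ... unused.
#' @return tibble with one row per unordered dyad: `unit_a`, `unit_b`,
#'   `n_joint`, `n_a_only`, `n_b_only`, `n_union`, `ai`, `defined`.
#' @method tidy assoc_matrix
#' @export
tidy.assoc_matrix <- function(x, ...) {
  idx <- which(upper.tri(x$ai), arr.ind = TRUE)
  n_a <- x$sightings[x$units[idx[, 1]]]
  n_b <- x$sightings[x$units[idx[, 2]]]
  tibble::tibble(
    unit_a = x$units[idx[, 1]],
    unit_b = x$units[idx[, 2]],
    n_joint = x$joint[idx],
    n_a_only = unname(n_a) - x$joint[idx],
    n_b_only = unname(n_b) - x$joint[idx],
    n_union = x$n_union[idx],
    ai = ifelse(x$defined[idx], x$ai[idx], NA_real_),
    defined = x$defined[idx]
  )
}

#' @rdname tidy.assoc_matrix
#' @method glance assoc_matrix
#' @export
glance.assoc_matrix <- function(x, ...) {
  d <- tidy(x)
  ok <- d$defined
  tibble::tibble(
    n_units = length(x$units), n_scans = x$n_scans,
    n_dyads = nrow(d), n_defined = sum(ok),
    mean_ai = mean(d$ai[ok]), cv_ai = cv_pop(d$ai[ok])
  )
}

#' Export an association matrix
#'
#' `write_assoc_long()` writes the long dyad format
#' (`unit_a,unit_b,n_joint,n_a_only,n_b_only,ai`); `write_assoc_square()`
#' writes the square AI matrix with a header row and column.
#'
#' @param x an `assoc_matrix`.
#' @param path output CSV path.
#' @export
write_assoc_long <- function(x, path) {
  d <- tidy(x)
  utils::write.csv(
    as.data.frame(d[, c("unit_a", "unit_b", "n_joint", "n_a_only", "n_b_only", "ai")]),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_assoc_long
#' @export
write_assoc_square <- function(x, path) {
  utils::write.csv(as.data.frame(x$ai), path, row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Heatmap of an association matrix
#'
#' @param object an `assoc_matrix`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot assoc_matrix
#' @export
autoplot.assoc_matrix <- function(object, ...) {
  d <- tidy(object)
  d2 <- d[, c("unit_b", "unit_a", "ai")]
  names(d2) <- c("unit_a", "unit_b", "ai")
  both <- rbind(d[, c("unit_a", "unit_b", "ai")], d2)
  ggplot2::ggplot(both, ggplot2::aes(x = .data$unit_a, y = .data$unit_b,
                                     fill = .data$ai)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "AI") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
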