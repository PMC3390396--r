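#' Directional colocalization fractions between two focus channels
#'
#' A focus in channel A is scored as colocalized when at least one channel B
#' focus lies on the same chromosome of the same cell within `tolerance`
#' (fraction of SC length), and vice versa. Matching is by distance
#' threshold, not one-to-one assignment, so one focus may "contain" several
#' partners; the two directional fractions may differ (e.g. 93.1% of MER3
#' foci containing HEI10 against 97.5% of HEI10 foci containing MER3).
#'
#' The tolerance is the single most consequential free parameter of the
#' analysis and is always carried in the result.
#'
#' @param a,b Foci data frames (`cell_id`, `bivalent_id`, `position_frac`)
#'   holding one channel each. An empty channel is an error (the fraction is
#'   undefined, not 0).
#' @param tolerance Matching radius as a fraction of SC length, > 0
#'   (default 0.01).
#' @return Object of class `coloc_result`: `fraction_a_with_b`,
#'   `fraction_b_with_a`, `tolerance`, `n_a`, `n_b`.
#' @export
#' @examples
#' a <- data.frame(cell_id = "c", bivalent_id = "b1",
#'                 position_frac = c(0.2, 0.8))
#' coloc_fractions(a, a)  # identical channels: both fractions 1
coloc_fractions <- function(a, b, tolerance = 0.01) {
  check_foci <- function(x, nm) {
    stopifnot(is.data.frame(x))
    need <- c("cell_id", "bivalent_id", "position_frac")
    if (!all(need %in% names(x)))
      stop(sprintf("channel '%s' must have columns %s", nm,
                   paste(need, collapse = ", ")))
    if (nrow(x) == 0L)
      stop(sprintf("channel '%s' is empty: colocalization fraction undefined", nm))
    if (any(x$position_frac < 0 | x$position_frac > 1))
      stop(sprintf("channel '%s' has positions outside [0, 1]", nm))
  }
  if (!is.numeric(tolerance) || tolerance <= 0)
    stop("'tolerance' must be > 0")
  check_foci(a, "a"); check_foci(b, "b")

  frac_with <- function(query, ref) {
    ref_split <- split(ref$position_frac,
                       paste(ref$cell_id, ref$bivalent_id, sep = "/"))
    qkey <- paste(query$cell_id, query$bivalent_id, sep = "/")
    hit <- vapply(seq_len(nrow(query)), function(i) {
      refs <- ref_split[[qkey[[i]]]]
      !is.null(refs) && any(abs(refs - query$position_frac[[i]]) <= tolerance)
    }, logical(1))
    mean(hit)
  }
  structure(
    list(fraction_a_with_b = frac_with(a, b),
         fraction_b_with_a = frac_with(b, a),
         tolerance = tolerance, n_a = nrow(a), n_b = nrow(b)),
    class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    "Colocalization (tolerance %.3g SC fraction):\n  %.1f%% of A foci (n = %d) contain B\n  %.1f%% of B foci (n = %d) contain A\n",
    x$tolerance, 100 * x$fraction_a_with_b, x$n_a,
    100 * x$fraction_b_with_a, x$n_b))
  invisible(x)
}

#' Fraction of foci away from a per-chromosome reference position
#'
#' Used for centromere exclusion: the fraction of foci lying at distance
#' greater than `tolerance` (fraction of SC length) from the chromosome's
#' reference position (e.g. a centromere marker signal).
#'
#' @param foci Foci data frame (`cell_id`, `bivalent_id`, `position_frac`)
#'   of one channel.
#' @param reference Named numeric vector mapping `bivalent_id` to the
#'   reference position (fraction of SC length), or a two-column data frame
#'   (`bivalent_id`, `position_frac`). Every chromosome carrying foci must
#'   have a reference.
#' @param tolerance Exclusion radius as a fraction of SC length, > 0.
#' @return Fraction of foci outside the reference window, in `[0, 1]`.
#' @export
fraction_outside_reference <- function(foci, reference, tolerance = 0.01) {
  stopifnot(is.data.frame(foci),
            all(c("bivalent_id", "position_frac") %in% names(foci)))
  if (!is.numeric(tolerance) || tolerance <= 0)
    stop("'tolerance' must be > 0")
  if (nrow(foci) == 0L) stop("no foci: fraction undefined")
  if (is.data.frame(reference)) {
    stopifnot(all(c("bivalent_id", "position_frac") %in% names(reference)))
    reference <- setNames(reference$position_frac,
                          as.character(reference$bivalent_id))
  }
  missing_ref <- setdiff(unique(as.character(foci$bivalent_id)),
                         names(reference))
  if (length(missing_ref))
    stop("no reference position for chromosome(s): ",
         paste(missing_ref, collapse = ", "))
  ref_pos <- reference[as.character(foci$bivalent_id)]
  mean(abs(foci$position_frac - ref_pos) > tolerance)
}
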