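# Shared low-level helpers: Phred encoding, seeded evaluation, rounding.

# Phred+33 <-> integer conversion. `qual` is a character vector of quality
# strings; returns a list of integer vectors (one per read).
phred_decode <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

phred_encode <- function(scores) {
  vapply(scores, function(s) intToUtf8(s + 33L), character(1))
}

# Phred score at a single 1-based position for every read, vectorised by
# pasting the position's characters into one string.
phred_at <- function(qual, pos) {
  chars <- substr(qual, pos, pos)
  if (any(chars == "")) {
    abort("all quality strings must cover the requested position")
  }
  utf8ToInt(paste(chars, collapse = "")) - 33L
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` must be a single integer")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed tables in this field
#' conventionally round half up, so 0.05 at one decimal becomes 0.1.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(c(0.05, 0.15, 3.2733), 1)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

# sample() that never treats a scalar as 1:n.
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# Random DNA of length n (uniform base composition).
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Merge a tibble of 0-based half-open intervals (columns start, end) into a
# disjoint sorted set using IRanges.
merge_intervals <- function(start, end) {
  if (length(start) == 0) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  r <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
  tibble::tibble(start = IRanges::start(r) - 1L, end = IRanges::end(r))
}

# Intersect two interval sets given as tibbles with start/end (0-based
# half-open); returns the intersection in the same representation.
intersect_intervals <- function(a, b) {
  ra <- IRanges::IRanges(start = a$start + 1L, end = a$end)
  rb <- IRanges::IRanges(start = b$start + 1L, end = b$end)
  r <- IRanges::intersect(ra, rb)
  tibble::tibble(start = IRanges::start(r) - 1L, end = IRanges::end(r))
}

# Subtract interval set b from a (both 0-based half-open tibbles).
setdiff_intervals <- function(a, b) {
  ra <- IRanges::IRanges(start = a$start + 1L, end = a$end)
  rb <- IRanges::IRanges(start = b$start + 1L, end = b$end)
  r <- IRanges::setdiff(ra, rb)
  tibble::tibble(start = IRanges::start(r) - 1L, end = IRanges::end(r))
}

interval_width <- function(x) sum(x$end - x$start)

# Is position p (0-based) inside any interval of set x?
positions_in_intervals <- function(pos, x) {
  if (nrow(x) == 0) return(rep(FALSE, length(pos)))
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(start = pos + 1L, width = 1L),
    IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
  seq_along(pos) %in% S4Vectors::queryHits(hits)
}
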