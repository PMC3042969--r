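#' Convert a Haldane map distance to a recombination fraction
#'
#' Uses the Haldane map function, which assumes crossovers occur as a Poisson
#' process with no interference: `r = 0.5 * (1 - exp(-0.02 * d))` for a
#' distance `d` in centiMorgans. Under this function a 10 cM interval
#' corresponds to r = 0.0906 and a 20 cM interval to r = 0.1648.
#'
#' @param distance_cM Numeric vector of non-negative map distances in cM.
#' @return Numeric vector of recombination fractions in `[0, 0.5)`.
#' @seealso [recomb_to_map()] for the inverse.
#' @examples
#' map_to_recomb(c(0, 10, 20))
#' @export
map_to_recomb <- function(distance_cM) {
  if (any(is.na(distance_cM)) || any(distance_cM < 0)) {
    stop("map distances must be non-negative", call. = FALSE)
  }
  0.5 * (1 - exp(-0.02 * distance_cM))
}

#' Convert a recombination fraction to a Haldane map distance
#'
#' @param r Numeric vector of recombination fractions in `[0, 0.5)`.
#' @return Map distances in cM.
#' @export
recomb_to_map <- function(r) {
  if (any(is.na(r)) || any(r < 0) || any(r >= 0.5)) {
    stop("recombination fractions must lie in [0, 0.5)", call. = FALSE)
  }
  -50 * log(1 - 2 * r)
}

#' Construct a genetic map
#'
#' A genetic map is a data frame with columns `chrom`, `marker` and `pos_cM`
#' giving ordered marker positions per chromosome (0-based at the first
#' marker of each chromosome). All positions are interpreted through the
#' Haldane map function (no crossover interference).
#'
#' @param chrom Character or factor vector of chromosome identifiers.
#' @param marker Character vector of marker names, unique genome-wide.
#' @param pos_cM Numeric vector of positions in cM, strictly increasing
#'   within each chromosome.
#' @return A `genetic_map` object (a validated data frame).
#' @export
genetic_map <- function(chrom, marker, pos_cM) {
  map <- data.frame(chrom = as.character(chrom), marker = as.character(marker),
                    pos_cM = as.numeric(pos_cM), stringsAsFactors = FALSE)
  validate_map(map)
  class(map) <- c("genetic_map", "data.frame")
  map
}

validate_map <- function(map) {
  stopifnot(all(c("chrom", "marker", "pos_cM") %in% names(map)))
  if (anyDuplicated(map$marker)) {
    stop("marker ids must be unique genome-wide", call. = FALSE)
  }
  if (any(is.na(map$pos_cM)) || any(map$pos_cM < 0)) {
    stop("marker positions must be non-negative numbers", call. = FALSE)
  }
  for (ch in unique(map$chrom)) {
    p <- map$pos_cM[map$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop(sprintf("marker positions on chromosome %s must be strictly increasing", ch),
           call. = FALSE)
    }
  }
  invisible(map)
}

#' Build a regular grid map
#'
#' Convenience constructor for a map of `n_chrom` chromosomes each carrying
#' `n_markers` markers at a fixed spacing — the layout used throughout the
#' package's simulation studies (5 chromosomes, 11 markers, 10 cM spacing).
#'
#' @param n_chrom Number of chromosomes.
#' @param n_markers Markers per chromosome.
#' @param spacing_cM Distance between adjacent markers in cM.
#' @return A `genetic_map`.
#' @export
grid_map <- function(n_chrom = 5, n_markers = 11, spacing_cM = 10) {
  chrom <- rep(paste0("C", seq_len(n_chrom)), each = n_markers)
  idx <- rep(seq_len(n_markers), n_chrom)
  genetic_map(chrom,
              marker = sprintf("M%d_%02d", rep(seq_len(n_chrom), each = n_markers), idx),
              pos_cM = (idx - 1) * spacing_cM)
}

# marker intervals of a map: one row per adjacent marker pair
map_intervals <- function(map) {
  out <- do.call(rbind, lapply(unique(map$chrom), function(ch) {
    sub <- map[map$chrom == ch, , drop = FALSE]
    m <- nrow(sub)
    if (m < 2) return(NULL)
    data.frame(chrom = ch,
               left = sub$marker[-m], right = sub$marker[-1],
               left_pos = sub$pos_cM[-m], right_pos = sub$pos_cM[-1],
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) out <- data.frame(chrom = character(), left = character(),
                                      right = character(), left_pos = numeric(),
                                      right_pos = numeric())
  out$interval <- seq_len(nrow(out))
  out
}
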