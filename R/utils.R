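#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, restoring the previous
#' RNG state afterwards so library code never clobbers the caller's stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream unchanged.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Canonical chromosome ordering: chr1..chr22, chrX, chrY first, anything else
# after in lexicographic order. Used everywhere "genome order" is needed.
chrom_rank <- function(chrom) {
  canon <- c(paste0("chr", 1:22), "chrX", "chrY")
  r <- match(chrom, canon)
  extra <- sort(unique(chrom[is.na(r)]))
  r[is.na(r)] <- length(canon) + match(chrom[is.na(r)], extra)
  r
}

genome_order <- function(chrom, start) order(chrom_rank(chrom), start)

#' Format a genome address in Mbp display style
#'
#' Renders a probe position as e.g. `"chr14:105.41"` (start in Mbp, two
#' decimals). Display only; base-pair integers stay authoritative and this
#' string is never parsed back.
#'
#' @param chrom Chromosome name(s).
#' @param start 0-based start position(s) in bp.
#' @return Character vector of display addresses.
#' @export
#' @examples
#' genome_address("chr14", 105410000)
genome_address <- function(chrom, start) {
  sprintf("%s:%.2f", chrom, start / 1e6)
}

stop_config <- function(...) stop("invalid-config: ", ..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
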