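# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# order variants by chromosome (order of first appearance) then position
.variant_order <- function(chrom, pos) {
  order(match(chrom, unique(chrom)), pos)
}

.check_positions <- function(chrom, pos) {
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("positions must be strictly increasing within chromosome '", ch, "'")
    }
  }
  invisible(TRUE)
}

.stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

# seeded evaluation that restores the caller's RNG state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}
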