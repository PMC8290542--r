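# Internal genotype coding shared by every stage:
#   0 = homozygous P1, 1 = heterozygous, 2 = homozygous P2, NA = missing.
GT_P1  <- 0L
GT_HET <- 1L
GT_P2  <- 2L

.PARENT_CALLS <- c("HOM_REF", "HOM_ALT", "HET", "MISSING")

# Sliding sums of a numeric/indicator vector over windows of w consecutive
# entries (one window per start index). cumsum-based, O(n).
.slidingSum <- function(v, w) {
  cs <- c(0, cumsum(v))
  cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]
}

# Fill NA entries with the nearest non-NA value (ties -> left neighbour).
.fillNearest <- function(x) {
  if (!anyNA(x)) return(x)
  idx <- which(!is.na(x))
  if (length(idx) == 0L) return(x)
  pos <- seq_along(x)
  left  <- idx[pmax(findInterval(pos, idx), 1L)]
  nxt   <- findInterval(pos, idx) + 1L
  right <- idx[pmin(pmax(nxt, 1L), length(idx))]
  use_right <- (abs(right - pos) < abs(pos - left))
  fill <- ifelse(use_right, right, left)
  out <- x
  out[is.na(x)] <- x[fill[is.na(x)]]
  out
}

.localSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(expr)
}
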