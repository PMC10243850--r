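# internal helpers shared across modules

# canonical key for an unordered gene pair; genes contain no whitespace,
# so "\r" cannot occur inside a symbol
.edgeKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

.splitKey <- function(key) {
  parts <- strsplit(key, "\r", fixed = TRUE)
  list(a = vapply(parts, `[[`, "", 1L), b = vapply(parts, `[[`, "", 2L))
}

# canonical edge table: gene_a < gene_b, sorted rows, no rownames
.makeEdges <- function(gene_a, gene_b, weight) {
  lo <- pmin(gene_a, gene_b)
  hi <- pmax(gene_a, gene_b)
  ord <- order(lo, hi)
  data.frame(gene_a = lo[ord], gene_b = hi[ord], weight = weight[ord],
             stringsAsFactors = FALSE, row.names = NULL)
}

# run expr under a temporary RNG state; leaves the caller's stream intact
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic child seed from a base seed and string tags; kept < 2^31
.deriveSeed <- function(seed, ...) {
  tags <- paste(c(...), collapse = "/")
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(tags)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Cosine distance between two vectors
#'
#' Distance is `1 - u.v / (|u| |v|)`, lying in \[0, 2\]. A pair of all-zero
#' vectors has distance 0; a zero vector against a non-zero vector has
#' distance 1, so degenerate fingerprints never propagate `NaN` through
#' benchmark loops.
#'
#' @param u,v Numeric vectors of equal length.
#' @return A single numeric distance.
#' @export
#' @examples
#' cosineDistance(c(1, 0), c(0, 1))  # orthogonal: 1
cosineDistance <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 && nv == 0) return(0)
  if (nu == 0 || nv == 0) return(1)
  1 - sum(u * v) / (nu * nv)
}

# dense cosine-distance matrix over the rows of a matrix
.cosineDistMatrix <- function(mat) {
  n <- nrow(mat)
  norms <- sqrt(rowSums(mat^2))
  cp <- tcrossprod(mat)
  D <- 1 - cp / outer(norms, norms)
  zero <- norms == 0
  if (any(zero)) {
    D[zero, ] <- 1
    D[, zero] <- 1
    D[zero, zero] <- 0
  }
  diag(D) <- 0
  # clip floating-point spill outside [0, 2]
  D[D < 0] <- 0
  D[D > 2] <- 2
  dimnames(D) <- list(rownames(mat), rownames(mat))
  D
}

# trapezoidal area under y over grid x
.aucTrapezoid <- function(x, y) pracma::trapz(x, y)

`%||%` <- function(a, b) if (is.null(a)) b else a
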