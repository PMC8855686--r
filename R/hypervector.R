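#' Hypervector algebra
#'
#' The package represents items as very high-dimensional vectors
#' (hypervectors). Atomic items (node labels, the unit weight) are *bipolar*:
#' every component is drawn i.i.d. uniformly from \{-1, +1\}. Composite
#' memories are exact integer componentwise sums of bipolar vectors -- no
#' clipping or re-bipolarization is ever applied, so all algebraic identities
#' (binding involution, bundling linearity) hold to machine precision.
#'
#' Three operations build structure:
#' \itemize{
#'   \item \code{hv_bind}: componentwise multiplication. Associates two
#'     vectors into one nearly orthogonal to both; self-inverse on bipolar
#'     vectors.
#'   \item \code{hv_bundle}: componentwise integer addition. Superposes a set
#'     so each member stays detectable by similarity.
#'   \item \code{hv_permute}: an invertible component reordering (cyclic
#'     shift by default) used to mark order/direction.
#' }
#' Similarity is the dot product divided by the dimension \code{D} -- not the
#' cosine. Dividing by \code{D} only keeps the additive signal/noise
#' decomposition of retrieval scores exact: the similarity of a bundle with a
#' probe is the sum of the member similarities.
#'
#' @name hypervector-algebra
NULL

#' Generate a codebook of random bipolar node hypervectors
#'
#' Assigns each node label an i.i.d. uniform bipolar hypervector of dimension
#' \code{D}. With dimension in the thousands, distinct entries are nearly
#' orthogonal: their pairwise similarity is approximately N(0, 1/D). Labels
#' are stored in sorted order so that the codebook -- and hence every
#' encoding built from it -- depends only on the label *set*, the dimension
#' and the seed, never on input row order.
#'
#' @param labels character vector of unique node labels (non-empty).
#' @param D hypervector dimension (positive integer; thousands in practice).
#' @param seed integer RNG seed; the same (labels, D, seed) always reproduces
#'   an identical codebook.
#' @return an object of class \code{hd_codebook}: a list with \code{labels}
#'   (sorted), \code{D}, \code{seed} and \code{H}, a \code{D x V} integer
#'   matrix whose columns are the node hypervectors (named by label).
#' @examples
#' cb <- generate_codebook(c("a", "b", "c"), D = 1000, seed = 1)
#' hv_similarity(node_hv(cb, "a"), node_hv(cb, "a"))  # exactly 1
#' @export
generate_codebook <- function(labels, D, seed) {
  labels <- as.character(labels)
  if (length(labels) == 0L) stop("`labels` must be non-empty", call. = FALSE)
  if (anyDuplicated(labels)) stop("duplicate node labels in codebook", call. = FALSE)
  if (!is_count(D)) stop("`D` must be a positive integer", call. = FALSE)
  labels <- sort(labels)
  V <- length(labels)
  H <- local_seed(seed, matrix(rbipolar(as.double(D) * V), nrow = D, ncol = V))
  colnames(H) <- labels
  structure(
    list(labels = labels, D = as.integer(D), seed = as.integer(seed), H = H),
    class = "hd_codebook"
  )
}

#' Look up a node hypervector in a codebook
#' @param cb an \code{hd_codebook}.
#' @param label a node label present in the codebook.
#' @return the node's bipolar hypervector (integer vector of length D).
#' @export
node_hv <- function(cb, label) {
  stopifnot(inherits(cb, "hd_codebook"))
  label <- as.character(label)
  if (length(label) != 1L || !(label %in% cb$labels)) {
    stop("unknown node label: ", paste(label, collapse = ", "), call. = FALSE)
  }
  cb$H[, label]
}

#' @export
print.hd_codebook <- function(x, ...) {
  cat("<hd_codebook> ", length(x$labels), " labels, D = ", x$D,
      ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Bind two hypervectors (componentwise product)
#'
#' Binding associates two hypervectors into a vector nearly orthogonal to
#' both constituents. On bipolar vectors it is an exact involution:
#' \code{hv_bind(a, hv_bind(a, x)) == x} componentwise for any integer
#' \code{x}, which is what makes unbinding-based retrieval exact up to
#' cross-term noise.
#'
#' @param a,b integer hypervectors of equal dimension.
#' @return the componentwise product.
#' @export
hv_bind <- function(a, b) {
  if (length(a) != length(b)) {
    stop("dimension mismatch in hv_bind: ", length(a), " vs ", length(b),
         call. = FALSE)
  }
  a * b
}

#' Bundle hypervectors (exact integer componentwise sum)
#'
#' @param vs non-empty list of hypervectors of equal dimension. Callers that
#'   want an "empty memory" must use an explicit zero vector.
#' @return the componentwise sum (integer-valued, unclipped).
#' @export
hv_bundle <- function(vs) {
  if (!is.list(vs) || length(vs) == 0L) {
    stop("hv_bundle needs a non-empty list of hypervectors", call. = FALSE)
  }
  D <- length(vs[[1L]])
  if (any(vapply(vs, length, 1L) != D)) {
    stop("dimension mismatch in hv_bundle", call. = FALSE)
  }
  Reduce(`+`, vs)
}

#' Permutation specifications
#'
#' The direction-marking permutation rho is, by default, a cyclic shift by
#' one position: it is invertible, composes by exponent arithmetic, and needs
#' no stored state in serialized memories. A seeded random permutation is
#' accepted as an alternative; its seed is recorded in encoding metadata.
#'
#' @param seed integer seed for the random permutation.
#' @return a permutation spec, a list with a \code{type} field.
#' @export
perm_cyclic <- function() list(type = "cyclic")

#' @rdname perm_cyclic
#' @export
perm_random <- function(seed) list(type = "random", seed = as.integer(seed))

# Row index vector implementing rho^p for dimension D under `spec`.
perm_index <- function(D, p, spec = perm_cyclic()) {
  p <- as.integer(p)
  if (identical(spec$type, "cyclic")) {
    return(((seq_len(D) - 1L - p) %% D) + 1L)
  }
  if (identical(spec$type, "random")) {
    base <- local_seed(spec$seed, sample.int(D))
    idx <- seq_len(D)
    if (p > 0) {
      for (k in seq_len(p)) idx <- base[idx]
    } else if (p < 0) {
      inv <- integer(D); inv[base] <- seq_len(D)
      for (k in seq_len(-p)) idx <- inv[idx]
    }
    return(idx)
  }
  stop("unknown permutation spec type: ", spec$type, call. = FALSE)
}

#' Permute a hypervector
#'
#' Applies the invertible permutation rho \code{p} times (negative \code{p}
#' applies the inverse). \code{hv_permute(hv_permute(h, p), -p)} recovers
#' \code{h} exactly; for \code{p != 0} the result is nearly orthogonal to the
#' input.
#'
#' @param h a hypervector.
#' @param p integer exponent (default 1).
#' @param spec a permutation spec from \code{\link{perm_cyclic}} or
#'   \code{\link{perm_random}}.
#' @return the permuted hypervector.
#' @export
hv_permute <- function(h, p = 1L, spec = perm_cyclic()) {
  h[perm_index(length(h), p, spec)]
}

#' Similarity of two hypervectors
#'
#' The decision statistic of the whole framework: the dot product divided by
#' the dimension. Identical bipolar vectors score exactly 1, independent ones
#' approximately N(0, 1/D). For integer bundles the same 1/D normalization is
#' kept (deliberately *not* cosine similarity) so that similarity is linear
#' in each argument.
#'
#' @param a,b hypervectors of equal dimension.
#' @return a real number.
#' @export
hv_similarity <- function(a, b) {
  if (length(a) != length(b)) {
    stop("dimension mismatch in hv_similarity: ", length(a), " vs ", length(b),
         call. = FALSE)
  }
  sum(as.double(a) * as.double(b)) / length(a)
}

#' Deterministic scalar-to-hypervector codec for edge weights
#'
#' A weight a in [0, 1) is represented by flipping a suffix of a fixed random
#' bipolar base vector (the encoding of the value 1): components up to
#' round(a * D) keep the base sign, the rest are negated. The similarity of
#' the encoding with the base is then exactly 2 * round(a*D)/D - 1, so
#' (similarity + 1)/2 decodes the weight at resolution 1/D. Nearby weights
#' give strongly correlated vectors, which is what keeps a whole family of
#' weights from exhausting capacity. Rounding uses round-half-to-even (base
#' R's \code{round}).
#'
#' @param D hypervector dimension.
#' @param seed integer seed for the base vector.
#' @return an object of class \code{hd_value_encoder} with fields
#'   \code{base}, \code{D}, \code{seed}.
#' @export
value_encoder <- function(D, seed) {
  if (!is_count(D)) stop("`D` must be a positive integer", call. = FALSE)
  base <- local_seed(seed, rbipolar(D))
  structure(list(base = base, D = as.integer(D), seed = as.integer(seed)),
            class = "hd_value_encoder")
}

#' @rdname value_encoder
#' @param a a real value in [0, 1].
#' @param enc an \code{hd_value_encoder}.
#' @return \code{encode_value}: the (bipolar) value hypervector;
#'   \code{decode_value}: the decoded scalar in [0, 1].
#' @export
encode_value <- function(a, enc) {
  stopifnot(inherits(enc, "hd_value_encoder"))
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a < 0 || a > 1) {
    stop("weight value must lie in [0, 1]: got ", a, call. = FALSE)
  }
  k <- round(a * enc$D)
  v <- enc$base
  if (k < enc$D) {
    flip <- (k + 1L):enc$D
    v[flip] <- -v[flip]
  }
  v
}

#' @rdname value_encoder
#' @param v a hypervector of dimension D (possibly noisy).
#' @export
decode_value <- function(v, enc) {
  stopifnot(inherits(enc, "hd_value_encoder"))
  if (length(v) != enc$D) {
    stop("dimension mismatch in decode_value", call. = FALSE)
  }
  min(1, max(0, (hv_similarity(v, enc$base) + 1) / 2))
}
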