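#' Randomly zero a fraction of hypervector components
#'
#' Emulates dropped dimensions/faulty neurons: exactly
#' \code{round(fraction * D)} uniformly chosen components are set to 0 (not
#' sign-flipped -- dropping removes both the signal and the noise
#' contribution of those components); the rest are untouched.
#'
#' @param h a hypervector.
#' @param fraction fraction of components to drop, in [0, 1].
#' @param seed integer seed.
#' @return the degraded hypervector.
#' @export
drop_dimensions <- function(h, fraction, seed = 1L) {
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction < 0 || fraction > 1) {
    stop("`fraction` must lie in [0, 1]", call. = FALSE)
  }
  D <- length(h)
  k <- round(fraction * D)
  if (k > 0) {
    idx <- local_seed(seed, sample.int(D, k))
    h[idx] <- 0L
  }
  h
}

MEMORY_FORMAT <- "hdgraph-memory"
MEMORY_VERSION <- 1L

#' Serialize / deserialize a graph memory
#'
#' The \code{.hdv} container is plain text: a first line holding a JSON
#' header (format tag, version, D, kind, codebook seed, value seed, node
#' labels, permutation spec) and a second line with the integer vector as
#' little-endian 32-bit values, base64-encoded. Loading validates the
#' format/version and that the payload length agrees with the header's D,
#' and reproduces a \code{graph_memory} equal to the original; the codebook
#' can be regenerated from the stored (labels, D, seed).
#'
#' @param G a \code{graph_memory}.
#' @param path file path (conventionally \code{*.hdv}).
#' @return \code{load_memory}: the reconstructed \code{graph_memory}.
#' @export
save_memory <- function(G, path) {
  stopifnot(inherits(G, "graph_memory"))
  v <- as.integer(round(G$vector))
  if (any(abs(G$vector - v) > 1e-9)) {
    stop("memory vector has non-integer components", call. = FALSE)
  }
  header <- jsonlite::toJSON(list(
    format = MEMORY_FORMAT, version = MEMORY_VERSION, D = G$D, kind = G$kind,
    codebook_seed = G$codebook_seed, value_seed = G$value_seed,
    node_labels = G$node_labels, perm = G$perm
  ), auto_unbox = TRUE, null = "null")
  payload <- jsonlite::base64_enc(writeBin(v, raw(), size = 4L,
                                           endian = "little"))
  payload <- gsub("[\r\n]", "", payload)
  writeLines(c(as.character(header), payload), path)
  invisible(path)
}

#' @rdname save_memory
#' @export
load_memory <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("truncated memory file", call. = FALSE)
  header <- jsonlite::fromJSON(lines[1L], simplifyVector = TRUE)
  if (!identical(header$format, MEMORY_FORMAT)) {
    stop("not an hdgraph memory file", call. = FALSE)
  }
  if (!identical(as.integer(header$version), MEMORY_VERSION)) {
    stop("unsupported memory format version: ", header$version, call. = FALSE)
  }
  raw <- jsonlite::base64_dec(paste(lines[-1L], collapse = ""))
  if (length(raw) %% 4L != 0L) stop("truncated payload", call. = FALSE)
  v <- readBin(raw, "integer", n = length(raw) %/% 4L, size = 4L,
               endian = "little")
  if (length(v) != header$D) {
    stop("header/payload length disagreement: D = ", header$D,
         " but payload holds ", length(v), " components", call. = FALSE)
  }
  structure(
    list(vector = v, D = as.integer(header$D), kind = header$kind,
         codebook_seed = as.integer(header$codebook_seed),
         value_seed = if (is.null(header$value_seed)) NULL else as.integer(header$value_seed),
         node_labels = as.character(header$node_labels),
         perm = {
           p <- as.list(header$perm)
           if (!is.null(p$seed)) p$seed <- as.integer(p$seed)
           p
         }),
    class = "graph_memory"
  )
}

#' Regenerate the codebook recorded in a memory's metadata
#' @param G a \code{graph_memory}.
#' @return the \code{hd_codebook} the memory was encoded with.
#' @export
codebook_from_memory <- function(G) {
  stopifnot(inherits(G, "graph_memory"))
  generate_codebook(G$node_labels, G$D, G$codebook_seed)
}
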