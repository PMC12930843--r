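#' Specify a peak-sequence embedder
#'
#' The Stage-1 network consumes a numeric embedding per peak sequence. The
#' embedder is pluggable: users running a large pretrained DNA language model
#' elsewhere load its output with `kind = "precomputed"`, while
#' `kind = "kmer_projection"` provides a fully deterministic in-package
#' embedder (k-mer composition followed by a seeded random projection) that
#' exercises the identical downstream path.
#'
#' @param kind `"kmer_projection"` or `"precomputed"`.
#' @param k k-mer length for the composition counts (default 4).
#' @param d Output embedding dimension.
#' @param seed Integer seed fixing the random projection.
#' @param normalize L2-normalize each count vector before projection.
#' @param projection `"gaussian"` (default) or `"identity"`; identity
#'   requires `d == 4^k` and returns raw (normalized) counts.
#' @param path For `precomputed`: TSV whose first column is `peak_id`
#'   followed by `d` numeric columns.
#' @return A list of class `embedder_spec`.
#' @export
embedder_spec <- function(kind = c("kmer_projection", "precomputed"),
                          k = 4L, d = 64L, seed = 1L, normalize = TRUE,
                          projection = c("gaussian", "identity"),
                          path = NULL) {
  kind <- match.arg(kind)
  projection <- match.arg(projection)
  stopifnot(k >= 1, d >= 1)
  if (kind == "precomputed" && is.null(path))
    stop("precomputed embedder needs a `path`")
  if (projection == "identity" && d != 4L^k)
    stop(sprintf("identity projection requires d == 4^k (= %d)", 4L^k))
  structure(list(kind = kind, k = as.integer(k), d = as.integer(d),
                 seed = as.integer(seed), normalize = isTRUE(normalize),
                 projection = projection, path = path),
            class = "embedder_spec")
}

#' Construct a peak embedding matrix
#'
#' @param values Numeric matrix, peaks x dimensions; all entries finite.
#' @param peak_ids Peak identifiers aligned to rows.
#' @return A list of class `peak_embedding_matrix`.
#' @export
peak_embedding_matrix <- function(values, peak_ids) {
  values <- as.matrix(values)
  peak_ids <- as.character(peak_ids)
  if (nrow(values) != length(peak_ids))
    stop("one embedding row per peak_id required")
  if (length(values) && !all(is.finite(values)))
    stop("peak embeddings must be finite")
  rownames(values) <- peak_ids
  structure(list(values = values, peak_ids = peak_ids, d = ncol(values)),
            class = "peak_embedding_matrix")
}

#' Embed peak sequences
#'
#' For `kmer_projection`: counts over the 4^k ACGT k-mers are taken per
#' sequence (windows containing N or any non-ACGT letter match no k-mer and
#' are dropped), optionally L2-normalized, then multiplied by a seed-fixed
#' Gaussian projection to `d` dimensions. For `precomputed`: rows are loaded
#' from `spec$path` keyed by the sequence names (peak ids).
#'
#' @param sequences Named character vector of ACGTN sequences (names are
#'   peak ids; required for `precomputed`).
#' @param spec An [embedder_spec()].
#' @return A [peak_embedding_matrix()], row i embedding sequence i.
#' @export
embed_peaks <- function(sequences, spec) {
  stopifnot(inherits(spec, "embedder_spec"))
  if (length(sequences) == 0) stop("no sequences to embed")
  bad <- grepl("[^ACGTN]", toupper(sequences))
  if (any(bad))
    stop(sprintf("sequence %d contains letters outside {A,C,G,T,N}", which(bad)[1]))
  ids <- names(sequences)
  if (is.null(ids)) ids <- sprintf("peak_%d", seq_along(sequences))
  if (spec$kind == "precomputed") {
    tab <- utils::read.delim(spec$path, stringsAsFactors = FALSE, check.names = FALSE)
    rn <- as.character(tab[[1]])
    missing <- setdiff(ids, rn)
    if (length(missing))
      stop(sprintf("precomputed embeddings missing peak_id(s): %s",
                   paste(utils::head(missing, 10), collapse = ", ")))
    vals <- as.matrix(tab[match(ids, rn), -1, drop = FALSE])
    storage.mode(vals) <- "double"
    return(peak_embedding_matrix(vals, ids))
  }
  counts <- kmer_counts(sequences, spec$k)
  if (spec$normalize) {
    nrm <- sqrt(rowSums(counts^2))
    nrm[nrm == 0] <- 1
    counts <- counts / nrm
  }
  if (spec$projection == "identity") {
    vals <- counts
  } else {
    proj <- local({
      set.seed(spec$seed)
      matrix(stats::rnorm(ncol(counts) * spec$d), ncol(counts), spec$d) / sqrt(spec$d)
    })
    vals <- counts %*% proj
  }
  dimnames(vals) <- NULL
  peak_embedding_matrix(vals, ids)
}

#' Count ACGT k-mers per sequence
#'
#' Windows containing any non-ACGT letter (e.g. N) match none of the 4^k
#' columns and so are dropped.
#'
#' @param sequences Character vector of sequences.
#' @param k k-mer length.
#' @return Integer matrix, sequences x 4^k, columns in lexicographic k-mer
#'   order (AA.., AC.., ...).
#' @export
kmer_counts <- function(sequences, k) {
  ss <- Biostrings::DNAStringSet(toupper(sequences))
  m <- Biostrings::oligonucleotideFrequency(ss, width = k)
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  m
}
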