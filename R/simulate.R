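#' Simulation settings for a reference/query scATAC pair
#'
#' Generates two datasets over a shared peak axis with known cell types.
#' Each peak is either a marker of exactly one type or background; a cell of
#' type t opens marker peaks of t with probability `p_open_marker` and all
#' other peaks with `p_open_background`. The target (query) domain carries a
#' batch effect: entries are additionally zeroed with probability
#' `batch_dropout` and its count layer is scaled by `depth_factor` (the
#' binary layer that every model component consumes is unaffected by depth).
#' Marker peaks also carry a planted type-specific sequence motif, giving
#' the sequence-embedding route a learnable signal.
#'
#' @param n_types Number of cell types (>= 2, default 4).
#' @param cells_per_type_source,cells_per_type_target Cells per type in each
#'   domain (default 100 each).
#' @param n_peaks Number of peaks (default 2000).
#' @param marker_fraction Fraction of peaks assigned as type-specific
#'   markers, split evenly across types (default 0.5).
#' @param p_open_marker,p_open_background Accessibility probabilities for a
#'   cell's own marker peaks vs all other peaks (defaults 0.8 and 0.05;
#'   `p_open_marker > p_open_background` required).
#' @param batch_dropout Extra per-entry zeroing probability in the target
#'   domain (default 0.3).
#' @param depth_factor Target count-depth multiplier (default 1).
#' @param peak_length Length of each simulated peak sequence (default 200).
#' @param motif_length Length of each type's planted motif (default 8).
#' @param seed Integer seed; outputs are byte-identical given the seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_types = 4L, cells_per_type_source = 100L,
                       cells_per_type_target = 100L, n_peaks = 2000L,
                       marker_fraction = 0.5, p_open_marker = 0.8,
                       p_open_background = 0.05, batch_dropout = 0.3,
                       depth_factor = 1, peak_length = 200L,
                       motif_length = 8L, seed = 1L) {
  stopifnot(n_types >= 2, cells_per_type_source >= 1, cells_per_type_target >= 1,
            n_peaks >= 1, marker_fraction > 0, marker_fraction <= 1,
            p_open_marker >= 0, p_open_marker <= 1,
            p_open_background >= 0, p_open_background <= 1,
            p_open_marker > p_open_background,
            batch_dropout >= 0, batch_dropout < 1, depth_factor > 0,
            peak_length >= 1, motif_length >= 1, motif_length <= peak_length)
  if (floor(marker_fraction * n_peaks) < n_types)
    stop("marker_fraction * n_peaks must be at least n_types")
  structure(list(n_types = as.integer(n_types),
                 cells_per_type_source = as.integer(cells_per_type_source),
                 cells_per_type_target = as.integer(cells_per_type_target),
                 n_peaks = as.integer(n_peaks),
                 marker_fraction = marker_fraction,
                 p_open_marker = p_open_marker,
                 p_open_background = p_open_background,
                 batch_dropout = batch_dropout, depth_factor = depth_factor,
                 peak_length = as.integer(peak_length),
                 motif_length = as.integer(motif_length),
                 seed = as.integer(seed)),
            class = "sim_config")
}

draw_domain <- function(cfg, n_cells_per_type, marker_of_peak, prefix,
                        dropout, depth_factor) {
  n_cells <- cfg$n_types * n_cells_per_type
  types <- rep(seq_len(cfg$n_types), each = n_cells_per_type)
  p <- matrix(cfg$p_open_background, n_cells, cfg$n_peaks)
  for (t in seq_len(cfg$n_types))
    p[types == t, marker_of_peak == t] <- cfg$p_open_marker
  open <- matrix(stats::rbinom(length(p), 1, p), n_cells, cfg$n_peaks)
  # count layer: open entries get 1 + Poisson extra reads, scaled by depth
  counts <- open * (1 + matrix(stats::rpois(length(p), 1), n_cells, cfg$n_peaks))
  counts <- counts * depth_factor
  if (dropout > 0) {
    keep <- matrix(stats::rbinom(length(p), 1, 1 - dropout), n_cells, cfg$n_peaks)
    counts <- counts * keep
  }
  ids <- sprintf("%s_cell_%04d", prefix, seq_len(n_cells))
  list(matrix = cell_peak_matrix(counts, ids,
                                 sprintf("chrSIM:%d-%d",
                                         (seq_len(cfg$n_peaks) - 1L) * cfg$peak_length,
                                         seq_len(cfg$n_peaks) * cfg$peak_length)),
       labels = label_table(ids, sprintf("type%02d", types),
                            levels = sprintf("type%02d", seq_len(cfg$n_types))))
}

#' Simulate a reference/query dataset pair with known labels
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `source` and `target` (each a list of
#'   `matrix`, a [cell_peak_matrix()], and `labels`, a [label_table()]),
#'   `peaks` (a [peak_set()]), `sequences` (named character vector with the
#'   planted motifs), `motifs` (one motif per type) and `marker_of_peak`
#'   (integer vector, 0 = background, otherwise the owning type). Target
#'   labels are returned for evaluation only and are never consumed by any
#'   training function.
#' @export
simulate_pair <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n_marker <- floor(cfg$marker_fraction * cfg$n_peaks)
  marker_peaks <- sample.int(cfg$n_peaks, n_marker)
  marker_of_peak <- integer(cfg$n_peaks)
  marker_of_peak[marker_peaks] <- rep_len(seq_len(cfg$n_types), n_marker)

  src <- draw_domain(cfg, cfg$cells_per_type_source, marker_of_peak, "ref",
                     dropout = 0, depth_factor = 1)
  tgt <- draw_domain(cfg, cfg$cells_per_type_target, marker_of_peak, "query",
                     dropout = cfg$batch_dropout,
                     depth_factor = cfg$depth_factor)

  bases <- c("A", "C", "G", "T")
  motifs <- vapply(seq_len(cfg$n_types), function(t)
    paste(sample(bases, cfg$motif_length, replace = TRUE), collapse = ""),
    character(1))
  seqs <- vapply(seq_len(cfg$n_peaks), function(j) {
    s <- sample(bases, cfg$peak_length, replace = TRUE)
    t <- marker_of_peak[j]
    if (t > 0) {
      pos <- sample.int(cfg$peak_length - cfg$motif_length + 1L, 1)
      s[pos:(pos + cfg$motif_length - 1L)] <- strsplit(motifs[t], "")[[1]]
    }
    paste(s, collapse = "")
  }, character(1))

  peaks <- peak_set(rep("chrSIM", cfg$n_peaks),
                    (seq_len(cfg$n_peaks) - 1L) * cfg$peak_length,
                    seq_len(cfg$n_peaks) * cfg$peak_length)
  names(seqs) <- peaks$peak_id
  list(source = src, target = tgt, peaks = peaks, sequences = seqs,
       motifs = motifs, marker_of_peak = marker_of_peak, config = cfg)
}

#' Write a simulated dataset pair to disk
#'
#' Emits the full fixture tree consumable by the annotation pipeline: MTX +
#' sidecars per domain, reference (and, for evaluation, target) labels as
#' TSV, peaks as BED and peak sequences as FASTA.
#'
#' @param sim Output of [simulate_pair()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (dom in c("source", "target")) {
    write_cell_peak_mtx(sim[[dom]]$matrix,
                        file.path(dir, paste0(dom, "_matrix.mtx")),
                        file.path(dir, paste0(dom, "_barcodes.tsv")),
                        file.path(dir, paste0(dom, "_peaks.tsv")))
    utils::write.table(sim[[dom]]$labels[, c("cell_id", "label")],
                       file.path(dir, paste0(dom, "_labels.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_peaks_bed(sim$peaks, file.path(dir, "peaks.bed"))
  writeLines(paste0(">", names(sim$sequences), "\n", sim$sequences),
             file.path(dir, "peaks.fa"))
  invisible(dir)
}

#' Accuracy and macro-F1 of predictions against ground truth
#'
#' Macro-F1 is the unweighted mean of per-class F1 over the union of true
#' and predicted classes; a class with zero precision+recall (or absent
#' from both predictions and truth on one side) contributes F1 = 0.
#'
#' @param predictions A data.frame with `cell_id` and `predicted_label`
#'   columns (as returned by [annotate_cells()]), or a character vector of
#'   labels named by cell id.
#' @param truth A [label_table()] over the same cells.
#' @return A list with `accuracy`, `macro_f1` and a `per_class` data.frame
#'   of precision/recall/F1.
#' @export
ground_truth_report <- function(predictions, truth) {
  if (is.data.frame(predictions)) {
    pred <- stats::setNames(predictions$predicted_label, predictions$cell_id)
  } else {
    pred <- predictions
  }
  stopifnot(inherits(truth, "label_table"))
  missing <- setdiff(truth$cell_id, names(pred))
  extra <- setdiff(names(pred), truth$cell_id)
  if (length(missing) || length(extra))
    stop(sprintf("cell id mismatch between predictions and truth (%d missing, %d extra)",
                 length(missing), length(extra)))
  pred <- pred[truth$cell_id]
  classes <- sort(union(unique(truth$label), unique(pred)))
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(pred == cl & truth$label == cl)
    fp <- sum(pred == cl & truth$label != cl)
    fn <- sum(pred != cl & truth$label == cl)
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
    data.frame(class = cl, precision = precision, recall = recall, f1 = f1,
               stringsAsFactors = FALSE)
  }))
  list(accuracy = mean(pred == truth$label),
       macro_f1 = mean(per_class$f1),
       per_class = per_class)
}
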