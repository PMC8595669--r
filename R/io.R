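# Plain-text genomic I/O: bedGraph, BED, BEDPE and TSV writers/readers.
# All coordinates on disk are 0-based half-open (BED convention).

#' Write a compartment track as bedGraph plus a state BED
#' @param track a `CompartmentTrack`.
#' @param bedgraph_path output bedGraph (chrom, start, end, pc1).
#' @param state_bed_path optional BED of A/B states.
#' @return `bedgraph_path`, invisibly.
#' @export
write_compartment_track <- function(track, bedgraph_path,
                                    state_bed_path = NULL) {
  chrom <- attr(track, "chrom")
  keep <- !is.na(track$pc1)
  data.table::fwrite(data.table::data.table(
    chrom = chrom, start = as.integer(track$start[keep]),
    end = as.integer(track$end[keep]), pc1 = track$pc1[keep]), bedgraph_path, sep = "\t", col.names = FALSE)
  if (!is.null(state_bed_path)) {
    ks <- keep & !is.na(track$state)
    data.table::fwrite(data.table::data.table(
      chrom = chrom, start = as.integer(track$start[ks]),
      end = as.integer(track$end[ks]), name = as.character(track$state[ks])), state_bed_path, sep = "\t",
      col.names = FALSE)
  }
  invisible(bedgraph_path)
}

#' Write an insulation track as bedGraph
#' @param t an `InsulationTrack`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_insulation_track <- function(t, path) {
  n <- length(t$score)
  keep <- !is.na(t$score)
  data.table::fwrite(data.table::data.table(
    chrom = t$chrom,
    start = as.integer((seq_len(n)[keep] - 1L) * t$resolution),
    end = as.integer(seq_len(n)[keep] * t$resolution),
    score = t$score[keep]),
    path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write intervals as BED
#' @param df data.frame with `chrom`, `start`, `end` and optional further
#'   columns appended as BED name/score fields.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  dt <- data.table::as.data.table(df)
  for (col in intersect(c("start", "end"), names(dt)))
    data.table::set(dt, j = col, value = as.integer(dt[[col]]))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write a loop list as BEDPE
#' @param loops a `LoopSet`.
#' @param path output path.
#' @param chrom chromosome name; default from the `LoopSet`.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(loops, path, chrom = attr(loops, "chrom")) {
  if (is.null(chrom)) chrom <- "chrS"
  data.table::fwrite(data.table::data.table(
    chrom1 = chrom, start1 = as.integer(loops$start1),
    end1 = as.integer(loops$end1),
    chrom2 = chrom, start2 = as.integer(loops$start2),
    end2 = as.integer(loops$end2),
    name = ".", score = loops$enrichment), path, sep = "\t",
    col.names = FALSE)
  invisible(path)
}

#' Read a BEDPE loop list
#' @param path BEDPE file.
#' @param resolution bin width used to recover bin indices.
#' @return a `LoopSet`-compatible data.frame with `bin1`, `bin2` and
#'   coordinate columns.
#' @export
read_bedpe <- function(path, resolution) {
  dt <- data.table::fread(path, header = FALSE)
  if (ncol(dt) < 6L) stop("BEDPE needs at least 6 columns")
  out <- data.frame(bin1 = as.integer(dt[[2]] / resolution) + 1L,
                    bin2 = as.integer(dt[[5]] / resolution) + 1L,
                    start1 = dt[[2]], end1 = dt[[3]],
                    start2 = dt[[5]], end2 = dt[[6]])
  class(out) <- c("LoopSet", "data.frame")
  attr(out, "resolution") <- resolution
  attr(out, "chrom") <- as.character(dt[[1]][1])
  out
}

#' Read a bedGraph signal track
#' @param path bedGraph file (chrom, start, end, value).
#' @return data.frame with `chrom`, `start`, `end`, `ratio`.
#' @export
read_bedgraph <- function(path) {
  dt <- data.table::fread(path, header = FALSE)
  if (ncol(dt) < 4L) stop("bedGraph needs 4 columns")
  data.frame(chrom = as.character(dt[[1]]), start = as.numeric(dt[[2]]),
             end = as.numeric(dt[[3]]), ratio = as.numeric(dt[[4]]))
}

#' Write a decay curve as 2-column TSV
#' @param curve a `DecayCurve`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_decay_curve <- function(curve, path) {
  data.table::fwrite(data.table::as.data.table(curve), path, sep = "\t")
  invisible(path)
}

#' Emit a simulated condition series to disk
#'
#' Writes each condition's matrix as triplet text, the activity reference
#' and truth tables as TSV — the same formats the pipeline consumes.
#'
#' @param sim result of [simulate_condition_series()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (cd in names(sim$matrices))
    write_matrix(sim$matrices[[cd]],
                 file.path(outdir, paste0(cd, ".triplet.tsv")))
  data.table::fwrite(data.table::data.table(activity = sim$activity),
                     file.path(outdir, "activity.tsv"), sep = "\t")
  data.table::fwrite(data.table::as.data.table(sim$truth$blocks),
                     file.path(outdir, "truth_blocks.tsv"), sep = "\t")
  invisible(outdir)
}
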