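# Percent-spliced-in quantification: classify spliced alignments against
# counting bins, then PSI = normalized inclusion / (inclusion + exclusion).

#' Count inclusion and exclusion evidence per counting bin
#'
#' For each counting bin of the model, a read supports *inclusion* when one
#' of its aligned blocks overlaps the bin, and *exclusion* when one of its
#' splice junctions (N gaps) spans the entire bin. A read contributes to a
#' given bin at most once. Only primary, mapped, non-duplicate alignments
#' with `MAPQ >= mapq_min` are counted.
#'
#' Position denominators give the number of distinct read placements that
#' could produce each read class (bin length + L - 1 for inclusion, L - 1
#' for exclusion, with L the modal aligned read length); `norm = "raw"`
#' sets both to 1.
#'
#' @param alignments One of: a path to a BAM or SAM file; a data.frame of
#'   alignment records with columns `pos` (1-based leftmost mapped
#'   position), `cigar`, and optionally `mapq` and `flag`; or a
#'   pre-tabulated counts data.frame (columns `sample_id`, `bin_id`,
#'   `inclusion_reads`, `exclusion_reads`, `inclusion_positions`,
#'   `exclusion_positions`), which is returned filtered to the model's bins.
#' @param model A `gene_model` whose bins are populated.
#' @param sample_id Sample label attached to the counts.
#' @param mapq_min Minimum mapping quality (default 10).
#' @param norm `"positions"` (default) or `"raw"`.
#' @return data.frame with one row per bin: `sample_id`, `bin_id`,
#'   `inclusion_reads`, `exclusion_reads`, `inclusion_positions`,
#'   `exclusion_positions`.
#' @export
count_bin_evidence <- function(alignments, model, sample_id,
                               mapq_min = 10L,
                               norm = c("positions", "raw")) {
  norm <- match.arg(norm)
  stopifnot(inherits(model, "gene_model"), !is.null(model$bins))
  bins <- model$bins

  if (is.data.frame(alignments) &&
      all(c("bin_id", "inclusion_reads", "exclusion_reads") %in%
          names(alignments))) {
    out <- alignments[alignments$bin_id %in% bins$bin_id, , drop = FALSE]
    if (!"sample_id" %in% names(out)) out$sample_id <- sample_id
    if (!"inclusion_positions" %in% names(out)) out$inclusion_positions <- 1L
    if (!"exclusion_positions" %in% names(out)) out$exclusion_positions <- 1L
    return(out[, c("sample_id", "bin_id", "inclusion_reads",
                   "exclusion_reads", "inclusion_positions",
                   "exclusion_positions")])
  }

  reads <- if (is.character(alignments)) {
    read_alignment_records(alignments)
  } else if (is.data.frame(alignments)) {
    alignments
  } else {
    stop("unsupported alignments input")
  }
  if (is.null(reads$mapq)) reads$mapq <- 255L
  if (is.null(reads$flag)) reads$flag <- 0L
  keep <- !is.na(reads$cigar) &
    bitwAnd(reads$flag, 4L) == 0L &      # mapped
    bitwAnd(reads$flag, 256L) == 0L &    # primary
    bitwAnd(reads$flag, 2048L) == 0L &   # not supplementary
    bitwAnd(reads$flag, 1024L) == 0L &   # not duplicate
    (!is.na(reads$mapq) & reads$mapq >= mapq_min)
  reads <- reads[keep, , drop = FALSE]

  bins_ir <- IRanges::IRanges(start = bins$start0 + 1L, end = bins$end0)
  n_bins <- nrow(bins)
  inc <- integer(n_bins)
  exc <- integer(n_bins)
  read_len <- 0L

  if (nrow(reads) > 0L) {
    blocks <- GenomicAlignments::extractAlignmentRangesOnReference(
      reads$cigar, pos = as.integer(reads$pos))
    qlen <- GenomicAlignments::cigarWidthAlongQuerySpace(
      reads$cigar, after.soft.clipping = TRUE)
    read_len <- as.integer(stats::median(qlen))

    flat <- unlist(blocks, use.names = FALSE)
    read_of_block <- rep(seq_len(nrow(reads)),
                         lengths(blocks))
    hits <- IRanges::findOverlaps(flat, bins_ir)
    pairs <- unique(data.frame(
      read = read_of_block[S4Vectors::queryHits(hits)],
      bin = S4Vectors::subjectHits(hits)))
    if (nrow(pairs) > 0L)
      inc <- tabulate(pairs$bin, nbins = n_bins)

    # introns: gaps between consecutive blocks of a read
    intr <- lapply(seq_along(blocks), function(i) {
      b <- blocks[[i]]
      if (length(b) < 2L) return(NULL)
      IRanges::IRanges(start = utils::head(IRanges::end(b), -1L) + 1L,
                       end = utils::tail(IRanges::start(b), -1L) - 1L)
    })
    nz <- which(!vapply(intr, is.null, logical(1)))
    if (length(nz) > 0L) {
      intr_flat <- do.call(c, intr[nz])
      read_of_intron <- rep(nz, vapply(intr[nz], length, integer(1)))
      jh <- IRanges::findOverlaps(bins_ir, intr_flat, type = "within")
      jp <- unique(data.frame(
        read = read_of_intron[S4Vectors::subjectHits(jh)],
        bin = S4Vectors::queryHits(jh)))
      if (nrow(jp) > 0L)
        exc <- tabulate(jp$bin, nbins = n_bins)
    }
  }

  if (norm == "positions" && read_len > 0L) {
    inc_pos <- pmax(bins$bin_length + read_len - 1L, 1L)
    exc_pos <- rep(max(read_len - 1L, 1L), n_bins)
  } else {
    inc_pos <- rep(1L, n_bins)
    exc_pos <- rep(1L, n_bins)
  }
  data.frame(sample_id = sample_id, bin_id = bins$bin_id,
             inclusion_reads = inc, exclusion_reads = exc,
             inclusion_positions = inc_pos, exclusion_positions = exc_pos,
             stringsAsFactors = FALSE)
}

# SAM/BAM -> data.frame(pos, cigar, mapq, flag)
read_alignment_records <- function(path) {
  ext <- tolower(tools::file_ext(path))
  bam <- path
  if (ext == "sam") {
    dest <- tempfile()
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = TRUE)
  }
  ga <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(
      what = c("flag", "mapq"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)))
  meta <- S4Vectors::mcols(ga)
  data.frame(pos = GenomicAlignments::start(ga),
             cigar = GenomicAlignments::cigar(ga),
             mapq = meta$mapq, flag = meta$flag,
             stringsAsFactors = FALSE)
}

#' Compute percent-spliced-in from bin counts
#'
#' PSI is the normalized inclusion rate
#' \deqn{\psi = \frac{I/P_I}{I/P_I + E/P_E}}
#' where I and E are inclusion and exclusion read counts and \eqn{P_I},
#' \eqn{P_E} their position denominators. PSI is `NA` when total support
#' `I + E` falls below `min_support`.
#'
#' @param counts data.frame as returned by [count_bin_evidence()].
#' @param min_support Minimum `inclusion_reads + exclusion_reads` for PSI
#'   to be reported (default 10).
#' @return data.frame `sample_id`, `bin_id`, `psi`, `total_support`.
#' @export
compute_psi <- function(counts, min_support = 10L) {
  stopifnot(all(c("inclusion_reads", "exclusion_reads") %in% names(counts)))
  ip <- if (is.null(counts$inclusion_positions)) 1 else counts$inclusion_positions
  ep <- if (is.null(counts$exclusion_positions)) 1 else counts$exclusion_positions
  if (any(ip < 1) || any(ep < 1)) stop("position denominators must be >= 1")
  if (any(counts$inclusion_reads < 0) || any(counts$exclusion_reads < 0))
    stop("negative read counts")
  support <- counts$inclusion_reads + counts$exclusion_reads
  inc_rate <- counts$inclusion_reads / ip
  exc_rate <- counts$exclusion_reads / ep
  psi <- ifelse(support >= min_support, inc_rate / (inc_rate + exc_rate),
                NA_real_)
  data.frame(sample_id = counts$sample_id, bin_id = counts$bin_id,
             psi = psi, total_support = as.integer(support),
             stringsAsFactors = FALSE)
}

#' Assemble a PSI table across samples
#'
#' Combines per-sample bin counts into one complete samples-by-bins PSI
#' table, attaching sample metadata. The table is deterministically ordered
#' (samples by id, bins by transcript position); bins with no counts in a
#' sample get `NA` PSI with zero support.
#'
#' @param counts data.frame of bin counts for all samples (rows from
#'   [count_bin_evidence()], possibly concatenated).
#' @param model The shared `gene_model`.
#' @param metadata data.frame with columns `sample_id`, `genotype`,
#'   `muscle`, covering every sample in `counts`.
#' @param min_support Passed to [compute_psi()].
#' @return An object of class `psi_table`: a list with elements `psi`
#'   (long data.frame `sample_id`, `bin_id`, `psi`, `total_support`),
#'   `metadata`, and `bin_order`.
#' @export
build_psi_table <- function(counts, model, metadata, min_support = 10L) {
  stopifnot(all(c("sample_id", "genotype", "muscle") %in% names(metadata)))
  samples <- sort(unique(counts$sample_id))
  missing_meta <- setdiff(samples, metadata$sample_id)
  if (length(missing_meta) > 0L)
    stop("metadata missing for sample(s): ",
         paste(missing_meta, collapse = ", "))
  bin_order <- model$bins$bin_id
  psi <- compute_psi(counts, min_support = min_support)
  grid <- expand.grid(bin_id = bin_order, sample_id = samples,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  m <- merge(grid, psi, by = c("sample_id", "bin_id"), all.x = TRUE)
  m$total_support[is.na(m$total_support)] <- 0L
  m <- m[order(m$sample_id, match(m$bin_id, bin_order)), ]
  rownames(m) <- NULL
  structure(list(psi = m,
                 metadata = metadata[match(samples, metadata$sample_id), ,
                                     drop = FALSE],
                 bin_order = bin_order),
            class = "psi_table")
}

#' @export
print.psi_table <- function(x, ...) {
  cat("<psi_table>", length(unique(x$psi$sample_id)), "samples x",
      length(x$bin_order), "bins;",
      sum(is.na(x$psi$psi)), "missing PSI values\n")
  invisible(x)
}

#' Write a PSI table to TSV
#'
#' @param table A `psi_table`.
#' @param path Output file; missing PSI is written as `NA`.
#' @return `path`, invisibly.
#' @export
write_psi_tsv <- function(table, path) {
  utils::write.table(table$psi, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a junction/body counts TSV
#'
#' Columns: `sample_id`, `bin_id`, `inclusion_reads`, `exclusion_reads`,
#' and optionally `inclusion_positions`, `exclusion_positions` (default 1).
#'
#' @param path TSV file.
#' @return Counts data.frame suitable for [build_psi_table()].
#' @export
read_counts_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(sample_id = "character",
                                          bin_id = "character"))
  need <- c("sample_id", "bin_id", "inclusion_reads", "exclusion_reads")
  if (!all(need %in% names(tab)))
    stop("counts TSV must have columns: ", paste(need, collapse = ", "))
  if (!"inclusion_positions" %in% names(tab)) tab$inclusion_positions <- 1L
  if (!"exclusion_positions" %in% names(tab)) tab$exclusion_positions <- 1L
  tab
}
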