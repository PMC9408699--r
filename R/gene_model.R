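# Transcript model: ordered exons, counting bins, named domain regions.
# Coordinates are 0-based half-open internally; 1-based inclusive at every
# I/O boundary (GTF/GFF3, TSV). exon_index follows transcript (5'->3') order,
# so on the minus strand (mouse Ttn) exon 1 is the genomically last exon.

#' Default titin domain regions
#'
#' Named exon ranges of the mouse titin transcript used throughout the
#' package: the Z-repeat region (ZR), the three PEVK segments and the
#' M-band exons (MEx). Two presets are provided for the PEVKI start exon
#' because the structural annotation places it at exon 112 while the
#' statistical analysis used 113; region bounds are otherwise identical and
#' non-overlapping (adjacent regions share a boundary exon in some
#' annotations -- the defaults here resolve that by starting each region one
#' exon after its neighbour ends).
#'
#' @param pevk_preset `"structural"` (PEVKI starts at exon 112, the default)
#'   or `"statistical"` (starts at 113).
#' @return A data.frame with columns `name`, `first_exon`, `last_exon`.
#' @export
#' @examples
#' titin_regions()
titin_regions <- function(pevk_preset = c("structural", "statistical")) {
  pevk_preset <- match.arg(pevk_preset)
  pevk1_start <- if (pevk_preset == "structural") 112L else 113L
  data.frame(
    name = c("ZR", "PEVKI", "PEVKII", "PEVKIII", "MEx"),
    first_exon = c(10L, pevk1_start, 136L, 156L, 342L),
    last_exon = c(14L, 135L, 155L, 209L, 347L),
    stringsAsFactors = FALSE
  )
}

#' Construct a gene model
#'
#' Low-level constructor. Most users should call [load_gene_model()].
#'
#' @param transcript_id Transcript identifier.
#' @param exons data.frame with columns `exon_index`, `start0`, `end0`
#'   (0-based half-open genomic), `coding_length`, `frame`. Rows must be in
#'   transcript order with strictly increasing `exon_index`.
#' @param chrom Chromosome / sequence name.
#' @param strand `"+"` or `"-"`.
#' @param regions data.frame of named exon ranges (`name`, `first_exon`,
#'   `last_exon`), or `NULL`.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(transcript_id, exons, chrom = "chr", strand = "+",
                       regions = NULL) {
  stopifnot(is.data.frame(exons),
            all(c("exon_index", "start0", "end0") %in% names(exons)))
  exons$exon_index <- as.integer(exons$exon_index)
  exons$start0 <- as.integer(exons$start0)
  exons$end0 <- as.integer(exons$end0)
  if (nrow(exons) == 0L) stop("gene model needs at least one exon")
  if (any(exons$end0 <= exons$start0))
    stop("zero- or negative-length exon in model")
  if (any(diff(exons$exon_index) <= 0L))
    stop("exon_index must be strictly increasing in transcript order")
  exons$length <- exons$end0 - exons$start0
  if (is.null(exons$coding_length)) exons$coding_length <- exons$length
  if (any(exons$coding_length > exons$length))
    stop("coding_length exceeds exon length")
  if (is.null(exons$frame))
    exons$frame <- as.integer(cumsum(c(0L, exons$coding_length[-nrow(exons)])) %% 3L)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (!is.null(regions)) {
    bad <- regions$first_exon > regions$last_exon
    if (any(bad)) stop("region with first_exon > last_exon: ",
                       paste(regions$name[bad], collapse = ", "))
  }
  m <- structure(
    list(transcript_id = transcript_id, chrom = chrom, strand = strand,
         exons = exons, bins = NULL, regions = regions),
    class = "gene_model"
  )
  m$bins <- default_bins(m)
  m
}

# one bin per exon, bin_id = exon_index
default_bins <- function(model) {
  e <- model$exons
  data.frame(
    bin_id = as.character(e$exon_index),
    parent_exon = e$exon_index,
    start0 = e$start0, end0 = e$end0,
    bin_length = e$end0 - e$start0,
    hang = FALSE,
    stringsAsFactors = FALSE
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> transcript", x$transcript_id,
      sprintf("(%s, %s strand)\n", x$chrom, x$strand))
  cat("  exons:", nrow(x$exons), "  bins:", nrow(x$bins),
      sprintf("(%d hang)\n", sum(x$bins$hang)))
  if (!is.null(x$regions))
    cat("  regions:", paste(x$regions$name, collapse = ", "), "\n")
  invisible(x)
}

#' Load a transcript model from GTF/GFF3 or a TSV exon table
#'
#' Reads the exon structure of one transcript. Exons are ordered 5'->3' in
#' transcript orientation (descending genomic coordinate on the minus
#' strand) and indexed from 1. Coding lengths are taken from CDS features
#' when present, otherwise each exon is assumed fully coding.
#'
#' @param path GTF, GFF3 (extensions .gtf/.gff/.gff3) or TSV file. A TSV
#'   must have columns `exon_index`, `chrom`, `start_1based`, `end_1based`,
#'   `strand`, and optionally `coding_length`, `frame`.
#' @param transcript_id Transcript to extract (GTF/GFF only; a TSV is taken
#'   as-is).
#' @param regions Optional region table as in [titin_regions()].
#' @return A `gene_model`.
#' @export
load_gene_model <- function(path, transcript_id = NULL,
                            regions = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gtf", "gff", "gff3")) {
    if (is.null(transcript_id))
      stop("transcript_id is required for GTF/GFF input")
    gr <- rtracklayer::import(path)
    meta <- S4Vectors::mcols(gr)
    tid <- as.character(meta$transcript_id)
    keep <- !is.na(tid) & tid == transcript_id
    if (!any(keep))
      stop("transcript '", transcript_id, "' not found in ", path)
    gr <- gr[keep]
    typ <- as.character(S4Vectors::mcols(gr)$type)
    ex <- gr[typ == "exon"]
    if (length(ex) == 0L)
      stop("transcript '", transcript_id, "' has no exon features")
    strand <- as.character(GenomicRanges::strand(ex))[1]
    if (!strand %in% c("+", "-")) strand <- "+"
    ord <- order(GenomicRanges::start(ex),
                 decreasing = (strand == "-"))
    ex <- ex[ord]
    cds <- gr[typ == "CDS"]
    start0 <- GenomicRanges::start(ex) - 1L
    end0 <- GenomicRanges::end(ex)
    coding <- end0 - start0
    if (length(cds) > 0L) {
      # per-exon coding length = total CDS overlap with the exon
      coding <- vapply(seq_along(ex), function(i) {
        hits <- IRanges::intersect(
          IRanges::IRanges(start0[i] + 1L, end0[i]),
          IRanges::reduce(IRanges::IRanges(GenomicRanges::start(cds),
                                           GenomicRanges::end(cds))))
        as.integer(sum(IRanges::width(hits)))
      }, integer(1))
    }
    exons <- data.frame(
      exon_index = seq_along(ex),
      start0 = start0, end0 = end0,
      coding_length = coding,
      stringsAsFactors = FALSE
    )
    chrom <- as.character(GenomicRanges::seqnames(ex))[1]
    gene_model(transcript_id, exons, chrom = chrom, strand = strand,
               regions = regions)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("exon_index", "chrom", "start_1based", "end_1based", "strand")
    if (!all(need %in% names(tab)))
      stop("TSV exon table must have columns: ", paste(need, collapse = ", "))
    tab <- tab[order(tab$exon_index), , drop = FALSE]
    exons <- data.frame(
      exon_index = tab$exon_index,
      start0 = tab$start_1based - 1L,
      end0 = tab$end_1based,
      stringsAsFactors = FALSE
    )
    if ("coding_length" %in% names(tab)) exons$coding_length <- tab$coding_length
    if ("frame" %in% names(tab)) exons$frame <- tab$frame
    tid <- if (!is.null(transcript_id)) transcript_id
           else if ("transcript_id" %in% names(tab)) tab$transcript_id[1]
           else "transcript"
    gene_model(tid, exons, chrom = tab$chrom[1], strand = tab$strand[1],
               regions = regions)
  }
}

#' Write a gene model to TSV
#'
#' Writes the exon table with 1-based inclusive coordinates, so that
#' [load_gene_model()] on the output reproduces the model exactly.
#'
#' @param model A `gene_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_model <- function(model, path) {
  e <- model$exons
  out <- data.frame(
    exon_index = e$exon_index,
    chrom = model$chrom,
    start_1based = e$start0 + 1L,
    end_1based = e$end0,
    strand = model$strand,
    coding_length = e$coding_length,
    frame = e$frame,
    transcript_id = model$transcript_id,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write counting bins as BED
#'
#' BED is 0-based half-open, matching the internal representation.
#'
#' @param model A `gene_model` with bins (see [flatten_to_bins()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bins_bed <- function(model, path) {
  b <- model$bins
  out <- data.frame(chrom = model$chrom, start = b$start0, end = b$end0,
                    name = b$bin_id, score = 0L, strand = model$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Split exons into counting bins at observed junction boundaries
#'
#' Counting bins are the unit of PSI quantification. An exon intersected
#' internally by a junction donor/acceptor is split into sub-bins labelled
#' `"<exon>.1"`, `"<exon>.2"`, ... in transcript order; a junction boundary
#' falling outside every annotated exon implies unannotated exonic sequence
#' contiguous with the nearest exon and produces a boundary-flanking
#' `"<exon>_hang"` bin. Only junctions supported by at least
#' `min_junction_reads` reads split the model, which keeps the binning
#' deterministic and evidence-driven.
#'
#' @param model A `gene_model`.
#' @param junctions data.frame with columns `start`, `end` (1-based
#'   inclusive genomic span of the intron, `start < end`) and optionally
#'   `count` (supporting reads; absent means trusted).
#' @param min_junction_reads Minimum read support for a junction boundary
#'   to be used (default 3).
#' @return The model with its `bins` table repopulated.
#' @export
flatten_to_bins <- function(model, junctions, min_junction_reads = 3L) {
  stopifnot(inherits(model, "gene_model"))
  if (is.null(junctions) || nrow(junctions) == 0L) {
    model$bins <- default_bins(model)
    return(model)
  }
  stopifnot(all(c("start", "end") %in% names(junctions)))
  if (any(junctions$start >= junctions$end))
    stop("junctions must have start < end (donor < acceptor)")
  if ("count" %in% names(junctions))
    junctions <- junctions[junctions$count >= min_junction_reads, , drop = FALSE]
  e <- model$exons
  span <- c(min(e$start0), max(e$end0))
  j0s <- junctions$start - 1L   # intron start, 0-based (right-boundary cut)
  j0e <- junctions$end          # intron end exclusive (left-boundary cut)
  inside <- j0s >= span[1] & j0e <= span[2]
  if (any(!inside)) {
    warning(sum(!inside), " junction(s) outside the transcript span ignored")
    j0s <- j0s[inside]; j0e <- j0e[inside]
  }
  right_cuts <- unique(j0s)  # exonic sequence ends here
  left_cuts <- unique(j0e)   # exonic sequence starts here
  all_cuts <- unique(c(right_cuts, left_cuts))

  bins <- list()
  for (i in seq_len(nrow(e))) {
    a <- e$start0[i]; b <- e$end0[i]
    cuts <- sort(all_cuts[all_cuts > a & all_cuts < b])
    edges <- c(a, cuts, b)
    n_sub <- length(edges) - 1L
    starts <- edges[-length(edges)]
    ends <- edges[-1]
    # transcript order of sub-bins: genomic on '+', reversed on '-'
    sub_rank <- if (model$strand == "+") seq_len(n_sub) else rev(seq_len(n_sub))
    ids <- if (n_sub == 1L) as.character(e$exon_index[i])
           else paste0(e$exon_index[i], ".", sub_rank)
    bins[[length(bins) + 1L]] <- data.frame(
      bin_id = ids, parent_exon = e$exon_index[i],
      start0 = starts, end0 = ends, bin_length = ends - starts,
      hang = FALSE, stringsAsFactors = FALSE)
  }

  in_exon <- function(p, open_left = FALSE) {
    # is genomic point p inside or on the boundary of an annotated exon
    any(p >= e$start0 & p <= e$end0)
  }
  hang <- list()
  for (p in left_cuts) {       # exonic begins at p going right
    if (any(p >= e$start0 & p < e$end0)) next  # inside an exon: handled above
    if (any(p == e$start0)) next               # annotated boundary
    cand <- e$start0[e$start0 > p]
    if (length(cand) == 0L) next
    a <- min(cand)
    if (any(e$end0 > p & e$end0 < a)) next     # gap overlaps another exon
    idx <- e$exon_index[e$start0 == a][1]
    hang[[length(hang) + 1L]] <- data.frame(
      bin_id = paste0(idx, "_hang"), parent_exon = idx,
      start0 = p, end0 = a, bin_length = a - p, hang = TRUE,
      stringsAsFactors = FALSE)
  }
  for (p in right_cuts) {      # exonic ends at p coming from the left
    if (any(p > e$start0 & p <= e$end0)) next
    if (any(p == e$end0)) next
    cand <- e$end0[e$end0 < p]
    if (length(cand) == 0L) next
    b <- max(cand)
    if (any(e$start0 < p & e$start0 > b)) next
    idx <- e$exon_index[e$end0 == b][1]
    hang[[length(hang) + 1L]] <- data.frame(
      bin_id = paste0(idx, "_hang"), parent_exon = idx,
      start0 = b, end0 = p, bin_length = p - b, hang = TRUE,
      stringsAsFactors = FALSE)
  }
  # hang bins extending into the same gap from both sides may collide:
  # keep non-overlap by clipping the later interval at the earlier one's end
  if (length(hang) > 1L) {
    h <- do.call(rbind, hang)
    h <- h[order(h$start0, h$end0), , drop = FALSE]
    run_end <- h$end0[1]
    for (i in 2:nrow(h)) {
      if (h$start0[i] < run_end) h$start0[i] <- min(run_end, h$end0[i])
      run_end <- max(run_end, h$end0[i])
    }
    h$bin_length <- h$end0 - h$start0
    h <- h[h$bin_length > 0L, , drop = FALSE]
    hang <- split(h, seq_len(nrow(h)))
  }
  bins <- do.call(rbind, c(bins, hang))
  # disambiguate rare double hangs on one exon
  dup <- duplicated(bins$bin_id)
  if (any(dup))
    bins$bin_id[dup] <- paste0(bins$bin_id[dup], ".2")
  ord <- order(bins$start0)
  if (model$strand == "-") ord <- rev(ord)
  model$bins <- bins[ord, , drop = FALSE]
  rownames(model$bins) <- NULL
  model
}

#' Exon indices covered by a named region
#'
#' @param model A `gene_model` with a region table.
#' @param region_name Region name, e.g. `"ZR"` or `"PEVKI"`.
#' @return Integer vector of exon indices in the region, all of which must
#'   exist in the model.
#' @export
exons_in_region <- function(model, region_name) {
  r <- model$regions
  if (is.null(r) || !region_name %in% r$name)
    stop("unknown region: ", region_name)
  r <- r[r$name == region_name, ]
  idx <- seq.int(r$first_exon, r$last_exon)
  missing <- setdiff(idx, model$exons$exon_index)
  if (length(missing) > 0L)
    stop("region ", region_name, " refers to exons absent from the model: ",
         paste(utils::head(missing, 5), collapse = ", "))
  as.integer(idx)
}

#' Amplicon design for splice-variant PCR
#'
#' Describes a PCR assay whose primers flank a run of optional
#' (alternatively spliced) exons: `flank_length` is the product size with
#' every optional exon excluded.
#'
#' @param flank_length Primer-to-primer span in bp with all optional exons
#'   excluded.
#' @param optional_exon_lengths Integer vector of optional exon lengths (bp).
#' @return An object of class `amplicon_design`.
#' @export
amplicon_design <- function(flank_length, optional_exon_lengths = integer()) {
  flank_length <- as.integer(flank_length)
  optional_exon_lengths <- as.integer(optional_exon_lengths)
  if (flank_length <= 0L) stop("flank_length must be positive")
  if (any(optional_exon_lengths <= 0L)) stop("exon lengths must be positive")
  structure(list(flank_length = flank_length,
                 optional_exon_lengths = optional_exon_lengths),
            class = "amplicon_design")
}

#' Predict the amplicon ladder of a splice-variant PCR
#'
#' Enumerates every subset of the optional exons and returns one row per
#' distinct product length: `flank_length` plus the summed lengths of the
#' included exons. With K equal-length optional exons this is the classic
#' K+1-band gel ladder.
#'
#' @param design An [amplicon_design()].
#' @return data.frame with columns `included_exons` and `length_bp`, sorted
#'   by decreasing length.
#' @export
#' @examples
#' predict_amplicons(amplicon_design(185, c(138, 138, 138)))
predict_amplicons <- function(design) {
  stopifnot(inherits(design, "amplicon_design"))
  lens <- design$optional_exon_lengths
  acc <- data.frame(included_exons = 0L, sum = 0L)
  for (l in lens) {
    plus <- acc
    plus$included_exons <- plus$included_exons + 1L
    plus$sum <- plus$sum + l
    acc <- rbind(acc, plus)
  }
  acc$length_bp <- design$flank_length + acc$sum
  # one entry per distinct product length; prefer the fewest-exon subset
  acc <- acc[order(acc$length_bp, acc$included_exons), ]
  acc <- acc[!duplicated(acc$length_bp), ]
  acc <- acc[order(-acc$length_bp), c("included_exons", "length_bp")]
  rownames(acc) <- NULL
  acc
}
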