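# Fixtures are built in code; independent oracles used across test files.

# regular toy transcript: n exons of length exon_len separated by gap
toy_model <- function(n_exons = 3, exon_len = 100, gap = 100, strand = "+",
                      regions = NULL) {
  starts <- (seq_len(n_exons) - 1) * (exon_len + gap)
  gene_model("toy",
             data.frame(exon_index = seq_len(n_exons),
                        start0 = starts, end0 = starts + exon_len),
             chrom = "chr", strand = strand, regions = regions)
}

write_toy_gtf <- function(path, strand = "+") {
  attr_tx <- 'gene_id "g1"; transcript_id "tx1";'
  lines <- c(
    sprintf("chr\ttest\texon\t1\t100\t.\t%s\t.\t%s", strand, attr_tx),
    sprintf("chr\ttest\texon\t201\t300\t.\t%s\t.\t%s", strand, attr_tx),
    sprintf("chr\ttest\texon\t401\t500\t.\t%s\t.\t%s", strand, attr_tx))
  writeLines(lines, path)
  path
}

# hand CIGAR parser for the brute-force oracle: reference blocks are maximal
# runs of M/D/=/X; N splits blocks (matches SAM semantics)
oracle_blocks <- function(pos, cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[A-Z=]$", "", ops))
  op <- sub("^\\d+", "", ops)
  blocks <- list()
  cur_start <- pos
  cur_end <- pos - 1L
  for (i in seq_along(op)) {
    if (op[i] %in% c("M", "D", "=", "X")) {
      cur_end <- cur_end + n[i]
    } else if (op[i] == "N") {
      if (cur_end >= cur_start)
        blocks[[length(blocks) + 1L]] <- c(cur_start, cur_end)
      cur_start <- cur_end + n[i] + 1L
      cur_end <- cur_start - 1L
    }
    # I, S, H, P consume no reference
  }
  if (cur_end >= cur_start)
    blocks[[length(blocks) + 1L]] <- c(cur_start, cur_end)
  blocks
}

# enumerate every read against every bin: inclusion if any block overlaps
# the bin, exclusion if any intron (gap between consecutive blocks) fully
# contains it; a read counts at most once per bin
oracle_bin_counts <- function(reads, model, mapq_min = 10) {
  bins <- model$bins
  inc <- integer(nrow(bins))
  exc <- integer(nrow(bins))
  for (r in seq_len(nrow(reads))) {
    flag <- if (is.null(reads$flag)) 0L else reads$flag[r]
    mapq <- if (is.null(reads$mapq)) 255L else reads$mapq[r]
    if (bitwAnd(flag, 4L) != 0L || bitwAnd(flag, 256L) != 0L ||
        bitwAnd(flag, 2048L) != 0L || bitwAnd(flag, 1024L) != 0L) next
    if (is.na(mapq) || mapq < mapq_min) next
    blocks <- oracle_blocks(reads$pos[r], reads$cigar[r])
    introns <- list()
    if (length(blocks) > 1L)
      for (i in seq_len(length(blocks) - 1L))
        introns[[i]] <- c(blocks[[i]][2] + 1L, blocks[[i + 1L]][1] - 1L)
    for (b in seq_len(nrow(bins))) {
      b1 <- bins$start0[b] + 1L
      b2 <- bins$end0[b]
      hit_inc <- any(vapply(blocks, function(x) x[1] <= b2 && x[2] >= b1,
                            logical(1)))
      hit_exc <- any(vapply(introns, function(x) x[1] <= b1 && x[2] >= b2,
                            logical(1)))
      if (hit_inc) inc[b] <- inc[b] + 1L
      if (hit_exc) exc[b] <- exc[b] + 1L
    }
  }
  data.frame(bin_id = bins$bin_id, inclusion_reads = inc,
             exclusion_reads = exc, stringsAsFactors = FALSE)
}

# random spliced/unspliced reads over a model's span
random_reads <- function(model, n) {
  span_end <- max(model$exons$end0)
  pos <- sample.int(span_end, n, replace = TRUE)
  cigar <- character(n)
  for (i in seq_len(n)) {
    kind <- sample(3, 1)
    if (kind == 1) {
      cigar[i] <- paste0(sample(20:60, 1), "M")
    } else if (kind == 2) {
      cigar[i] <- sprintf("%dM%dN%dM", sample(10:30, 1),
                          sample(30:400, 1), sample(10:30, 1))
    } else {
      cigar[i] <- sprintf("%dM%dN%dM%dN%dM", sample(5:20, 1),
                          sample(30:250, 1), sample(5:20, 1),
                          sample(30:250, 1), sample(5:20, 1))
    }
  }
  data.frame(pos = pos, cigar = cigar,
             mapq = sample(c(0L, 30L, 60L), n, replace = TRUE,
                           prob = c(0.1, 0.45, 0.45)),
             flag = sample(c(0L, 256L), n, replace = TRUE,
                           prob = c(0.9, 0.1)),
             stringsAsFactors = FALSE)
}

# direct design-matrix least-squares oracle for Type III two-way ANOVA
# with sum-to-zero contrasts: SS(effect) = RSS(model minus the effect's
# columns) - RSS(full model)
ls_anova_oracle <- function(d) {
  d$genotype <- factor(d$genotype)
  d$muscle <- factor(d$muscle)
  X <- stats::model.matrix(~ genotype * muscle, data = d,
                           contrasts.arg = list(genotype = "contr.sum",
                                                muscle = "contr.sum"))
  y <- d$psi
  rss <- function(M) {
    beta <- qr.coef(qr(M), y)
    sum((y - M %*% beta)^2)
  }
  asg <- attr(X, "assign")  # 0 = intercept, 1 = genotype, 2 = muscle, 3 = g:m
  rss_full <- rss(X)
  df_res <- nrow(X) - ncol(X)
  out <- lapply(1:3, function(term) {
    drop <- asg != term
    ss <- rss(X[, drop, drop = FALSE]) - rss_full
    df <- sum(asg == term)
    Fv <- (ss / df) / (rss_full / df_res)
    data.frame(term = term, df = df, F = Fv,
               p = stats::pf(Fv, df, df_res, lower.tail = FALSE))
  })
  do.call(rbind, out)
}

# builds a psi_table directly (bypassing the counting layer) for the
# comparison-module tests
make_psi_table <- function(psi_long, metadata, bin_order = NULL) {
  if (is.null(bin_order)) bin_order <- sort(unique(psi_long$bin_id))
  if (is.null(psi_long$total_support)) psi_long$total_support <- 100L
  structure(list(psi = psi_long, metadata = metadata, bin_order = bin_order),
            class = "psi_table")
}
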