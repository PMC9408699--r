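# Mass of an alternatively spliced exon range (the PEVK segment) estimated
# three ways from per-exon masses and PSI: minimum (constitutive exons
# only), maximum (every expressed exon), and PSI-weighted intermediate.

# standard average amino-acid residue masses (Da), monomer minus water
AA_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

#' Per-exon protein masses from the coding sequence
#'
#' Translates the transcript's coding sequence and assigns each residue's
#' average mass to exons. Masses are residue masses only (no terminal
#' water), so they are additive over exon ranges. A codon spanning an exon
#' boundary is apportioned pro rata by nucleotide count (1/3 of the residue
#' mass per nucleotide), so `aa_length` is a codon-equivalent count and may
#' be fractional at boundaries.
#'
#' @param model A `gene_model`; exon `coding_length` values define how the
#'   CDS distributes over exons.
#' @param cds Coding sequence: a character string, `Biostrings::DNAString`,
#'   or single-sequence `DNAStringSet`. Its length must equal the summed
#'   coding lengths and be a multiple of 3. A terminal stop codon is
#'   allowed and contributes no mass.
#' @return data.frame `exon_index`, `aa_length`, `mass_kda`.
#' @export
exon_masses_from_sequence <- function(model, cds) {
  stopifnot(inherits(model, "gene_model"))
  if (inherits(cds, "DNAStringSet")) cds <- cds[[1]]
  cds <- toupper(as.character(cds))
  e <- model$exons
  total <- sum(e$coding_length)
  if (nchar(cds) != total)
    stop("CDS length (", nchar(cds), ") does not match the summed exon ",
         "coding lengths (", total, ")")
  if (total %% 3L != 0L)
    stop("CDS length is not a multiple of 3")
  # exon owning each CDS position
  exon_of_pos <- rep(e$exon_index, e$coding_length)
  n_codon <- total %/% 3L
  codons <- substring(cds, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
  aa <- Biostrings::GENETIC_CODE[codons]
  bad <- which(is.na(aa))
  if (length(bad) > 0L)
    stop("unrecognized codon '", codons[bad[1]], "' at codon ", bad[1])
  stops <- which(aa == "*")
  if (any(stops < n_codon))
    stop("internal stop codon in exon ",
         exon_of_pos[3L * stops[stops < n_codon][1] - 2L])
  res_mass <- AA_RESIDUE_MASS[aa]
  res_mass[aa == "*"] <- 0
  aa_count <- as.numeric(aa != "*")
  # spread each codon's mass over its 3 nucleotides
  mass_per_nt <- rep(res_mass / 3, each = 3L)
  aa_per_nt <- rep(aa_count / 3, each = 3L)
  out <- data.frame(
    exon_index = e$exon_index,
    aa_length = as.numeric(tapply(aa_per_nt, factor(exon_of_pos,
                                                    levels = e$exon_index),
                                  sum, default = 0)),
    mass_kda = as.numeric(tapply(mass_per_nt, factor(exon_of_pos,
                                                     levels = e$exon_index),
                                 sum, default = 0)) / 1000,
    stringsAsFactors = FALSE)
  out$aa_length[is.na(out$aa_length)] <- 0
  out$mass_kda[is.na(out$mass_kda)] <- 0
  out
}

#' Estimate the expressed mass of an exon range from PSI
#'
#' Three estimators of the protein mass contributed by an alternatively
#' spliced exon range, given each exon's mass and its group-level PSI:
#' the minimum (only exons with PSI = 1), the maximum (every exon with
#' PSI > 0), and the PSI-weighted intermediate (sum of mass times PSI),
#' which treats PSI as the expected inclusion probability of each exon.
#' Estimated PSI within `psi_tolerance` of 0 or 1 is snapped to exactly
#' 0 or 1 before all three estimators, which makes the comparison with
#' exact 0/1 well-posed on floating-point estimates and preserves the
#' ordering `mass_min <= mass_weighted <= mass_max` for every PSI vector.
#'
#' @param masses data.frame with columns `exon_index`, `mass_kda` (e.g.
#'   from [exon_masses_from_sequence()] or a user table).
#' @param psi Named numeric vector (names = exon indices) or data.frame
#'   with columns `exon_index`, `psi`, giving group-level PSI per exon.
#' @param region,group Labels attached to the estimate.
#' @param psi_tolerance Snapping tolerance for the 0/1 comparisons
#'   (default 0.005).
#' @param impute If `TRUE`, exons with missing PSI get the mean PSI of the
#'   non-missing exons; the default is an error, because silent imputation
#'   would corrupt the headline mass figures.
#' @return A `segment_mass_estimate` with fields `mass_min`, `mass_max`,
#'   `mass_weighted` (kDa).
#' @export
#' @examples
#' estimate_segment_mass(data.frame(exon_index = 1:2, mass_kda = c(10, 20)),
#'                       c("1" = 1, "2" = 0.5))
estimate_segment_mass <- function(masses, psi, region = "segment",
                                  group = NA_character_,
                                  psi_tolerance = 0.005, impute = FALSE) {
  stopifnot(is.data.frame(masses),
            all(c("exon_index", "mass_kda") %in% names(masses)))
  if (nrow(masses) == 0L) stop("no massed exons in the region")
  if (is.data.frame(psi)) {
    v <- psi$psi
    names(v) <- as.character(psi$exon_index)
    psi <- v
  }
  p <- psi[as.character(masses$exon_index)]
  if (anyNA(p)) {
    if (!impute)
      stop("missing PSI for exon(s): ",
           paste(masses$exon_index[is.na(p)], collapse = ", "),
           " (set impute = TRUE to use the group mean)")
    p[is.na(p)] <- mean(p, na.rm = TRUE)
  }
  if (any(p < 0 | p > 1)) stop("PSI values must lie in [0, 1]")
  p[p >= 1 - psi_tolerance] <- 1
  p[p <= psi_tolerance] <- 0
  m <- masses$mass_kda
  structure(list(region = region, group = group,
                 mass_min = sum(m[p == 1]),
                 mass_max = sum(m[p > 0]),
                 mass_weighted = sum(m * p),
                 psi_tolerance = psi_tolerance),
            class = "segment_mass_estimate")
}

#' Construct a segment mass estimate from reported values
#'
#' Wraps externally computed (e.g. published) mass figures so they can be
#' compared with [mass_difference()].
#'
#' @param region,group Labels.
#' @param mass_weighted PSI-weighted (intermediate) mass, kDa.
#' @param mass_min,mass_max Optional bracketing estimates, kDa.
#' @return A `segment_mass_estimate`.
#' @export
segment_mass_estimate <- function(region, group, mass_weighted,
                                  mass_min = NA_real_, mass_max = NA_real_) {
  structure(list(region = region, group = group,
                 mass_min = mass_min, mass_max = mass_max,
                 mass_weighted = mass_weighted, psi_tolerance = NA_real_),
            class = "segment_mass_estimate")
}

#' @export
print.segment_mass_estimate <- function(x, ...) {
  cat(sprintf("<segment_mass_estimate> %s%s: min %.1f / weighted %.1f / max %.1f kDa\n",
              x$region, if (is.na(x$group)) "" else paste0(" [", x$group, "]"),
              x$mass_min, x$mass_weighted, x$mass_max))
  invisible(x)
}

#' Mass difference between two segment estimates
#'
#' Reference (e.g. wild-type) minus comparison (e.g. mutant) mass on the
#' kDa scale, for a chosen estimator. Both estimates must describe the same
#' region. Rounding is left to the caller at report time.
#'
#' @param wt,mut `segment_mass_estimate` objects for the same region.
#' @param mode `"weighted"` (default), `"min"`, or `"max"`.
#' @return Numeric difference in kDa (`wt - mut`).
#' @export
mass_difference <- function(wt, mut, mode = c("weighted", "min", "max")) {
  mode <- match.arg(mode)
  stopifnot(inherits(wt, "segment_mass_estimate"),
            inherits(mut, "segment_mass_estimate"))
  if (!identical(wt$region, mut$region))
    stop("estimates describe different regions: ", wt$region, " vs ",
         mut$region)
  field <- paste0("mass_", mode)
  a <- wt[[field]]; b <- mut[[field]]
  if (is.na(a) || is.na(b))
    stop("mode '", mode, "' is not available in both estimates")
  a - b
}
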