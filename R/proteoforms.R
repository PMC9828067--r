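# Proteoform toolkit: ABri / ADan / amyloid-beta peptide species,
# theoretical masses, hydrophobic fractions, subgroup classification.

# Monoisotopic residue masses (Da), standard one-letter codes.
.AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
.MASS_WATER    <- 18.010565
.MASS_AMMONIA  <- 17.026549
.MASS_HYDROGEN <- 1.007825
.MASS_PROTON   <- 1.00727646

# Residues counted as hydrophobic. The class {A,F,I,L,M,V,W} reproduces
# every printed reference percentage for the ABri/ADan/Abeta truncation
# series under round-to-one-decimal (Cys, Gly, Tyr excluded).
.HYDROPHOBIC <- c("A", "F", "I", "L", "M", "V", "W")

.pf_cache <- new.env(parent = emptyenv())

#' Amyloid peptide region sequences
#'
#' Returns the full amyloid peptide region for each precursor: the
#' 34-residue ABri and ADan peptides released from mutant BRI2 (identical
#' over residues 1-22, divergent C-termini) and residues 1-42 of the
#' APP-derived amyloid-beta peptide. Sequences are shipped as a plain-text
#' fixture; loading fails if a sequence length contradicts its canonical
#' span.
#'
#' @return Named character vector with elements `ABri`, `ADan`, `Abeta`.
#' @export
amyloid_sequences <- function() {
  if (!is.null(.pf_cache$sequences)) return(.pf_cache$sequences)
  path <- system.file("extdata", "amyloid_sequences.json", package = "vesselmap")
  reg <- jsonlite::read_json(path, simplifyVector = TRUE)
  seqs <- unlist(reg$sequences)
  spans <- unlist(reg$canonical_c_terminus)
  for (p in names(seqs)) {
    if (nchar(seqs[[p]]) != spans[[p]])
      stop("sequence registry corrupt: ", p, " has length ", nchar(seqs[[p]]),
           " but canonical span ", spans[[p]])
  }
  .pf_cache$sequences <- seqs
  .pf_cache$spans <- spans
  seqs
}

#' Canonical C-terminal residue of a precursor's amyloid region
#'
#' 34 for ABri/ADan, 42 for amyloid-beta.
#'
#' @param precursor `"ABri"`, `"ADan"` or `"Abeta"`.
#' @return Integer position.
#' @export
canonical_c_terminus <- function(precursor) {
  amyloid_sequences()
  precursor <- match.arg(precursor, names(.pf_cache$spans))
  unname(.pf_cache$spans[[precursor]])
}

#' Construct a proteoform species
#'
#' A proteoform is a specific molecular form of an amyloid peptide: a
#' residue span of the precursor's amyloid region, optionally N-terminally
#' pyroglutamated, with zero or more intramolecular disulfide bonds.
#'
#' @param precursor `"ABri"`, `"ADan"` or `"Abeta"`.
#' @param start,end 1-based inclusive residue span within the amyloid
#'   region.
#' @param pyroglu Logical; N-terminal pyroglutamate (requires Glu or Gln at
#'   `start`).
#' @param disulfides Number of intramolecular disulfide bonds; at most
#'   `floor(nCys / 2)` over the spanned sequence.
#' @param name Display name; derived (e.g. `"ABri1pE-34"`) when `NULL`.
#' @return Object of class `proteoform`.
#' @examples
#' proteoform("ABri", 1, 34, pyroglu = TRUE, disulfides = 1)
#' @export
proteoform <- function(precursor, start, end, pyroglu = FALSE,
                       disulfides = 0L, name = NULL) {
  seqs <- amyloid_sequences()
  precursor <- match.arg(precursor, names(seqs))
  start <- as.integer(start); end <- as.integer(end)
  len <- nchar(seqs[[precursor]])
  if (is.na(start) || is.na(end) || start < 1L || start > end || end > len)
    stop("span [", start, ", ", end, "] outside amyloid region 1-", len,
         " of ", precursor)
  sq <- substr(seqs[[precursor]], start, end)
  first <- substr(sq, 1, 1)
  if (isTRUE(pyroglu) && !first %in% c("E", "Q"))
    stop("pyroglutamate requires Glu or Gln at the N-terminus, found ", first)
  n_cys <- sum(strsplit(sq, "")[[1]] == "C")
  disulfides <- as.integer(disulfides)
  if (disulfides < 0L || disulfides > n_cys %/% 2L)
    stop("disulfide count ", disulfides, " exceeds floor(nCys/2) = ",
         n_cys %/% 2L)
  if (is.null(name))
    name <- paste0(precursor, start, if (isTRUE(pyroglu)) "pE", "-", end)
  structure(
    list(precursor = precursor, start = start, end = end,
         pyroglu = isTRUE(pyroglu), disulfides = disulfides,
         display_name = name),
    class = "proteoform")
}

#' @export
print.proteoform <- function(x, ...) {
  cat(x$display_name, ": ", get_sequence(x),
      if (x$disulfides > 0) paste0(" [", x$disulfides, " S-S]"), "\n", sep = "")
  invisible(x)
}

#' Amino-acid sequence of a proteoform
#'
#' Extracts the subsequence `[start, end]` of the precursor amyloid region.
#'
#' @param x A [proteoform], or a precursor name when `start`/`end` given.
#' @param start,end Optional residue span when `x` is a precursor name.
#' @return One-letter amino-acid string.
#' @export
get_sequence <- function(x, start = NULL, end = NULL) {
  if (inherits(x, "proteoform"))
    return(substr(amyloid_sequences()[[x$precursor]], x$start, x$end))
  x <- proteoform(x, start, end)  # validates span
  substr(amyloid_sequences()[[x$precursor]], x$start, x$end)
}

#' Monoisotopic mass of a peptide sequence
#'
#' Sum of residue monoisotopic masses plus one water, minus 18.010565 Da per
#' pyroglutamate formed from Glu (17.026549 Da from Gln), minus
#' 2 x 1.007825 Da per disulfide bond.
#'
#' @param sequence One-letter amino-acid string.
#' @param pyroglu N-terminal pyroglutamate.
#' @param disulfides Number of disulfide bonds.
#' @return Mass in Da.
#' @examples
#' peptide_mass("GG")  # 132.0535
#' @export
peptide_mass <- function(sequence, pyroglu = FALSE, disulfides = 0L) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  if (length(aa) == 0) stop("empty sequence")
  unknown <- setdiff(aa, names(.AA_MONO))
  if (length(unknown))
    stop("unknown residue code(s): ", paste(unique(unknown), collapse = ", "))
  m <- sum(.AA_MONO[aa]) + .MASS_WATER
  if (isTRUE(pyroglu)) {
    if (aa[1] == "E") m <- m - .MASS_WATER
    else if (aa[1] == "Q") m <- m - .MASS_AMMONIA
    else stop("pyroglutamate requires Glu or Gln at the N-terminus, found ", aa[1])
  }
  m - 2 * .MASS_HYDROGEN * as.integer(disulfides)
}

#' Monoisotopic mass of a proteoform species
#'
#' @param species A [proteoform].
#' @return Mass in Da.
#' @export
monoisotopic_mass <- function(species) {
  stopifnot(inherits(species, "proteoform"))
  peptide_mass(get_sequence(species), pyroglu = species$pyroglu,
               disulfides = species$disulfides)
}

#' Singly protonated m/z of a proteoform species
#'
#' `[M+H]+` assuming charge 1, as observed in linear-TOF MALDI of amyloid
#' peptides.
#'
#' @param species A [proteoform] or a species table (see [species_preset]).
#' @return Numeric m/z (vector for a table).
#' @export
species_mz <- function(species) {
  if (is.data.frame(species))
    return(vapply(seq_len(nrow(species)), function(i)
      species_mz(as_proteoform(species[i, ])), numeric(1)))
  monoisotopic_mass(species) + .MASS_PROTON
}

.round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Hydrophobic residue fraction of a peptide
#'
#' Percentage of residues in the hydrophobic class
#' \{Ala, Phe, Ile, Leu, Met, Val, Trp\}, reported to one decimal place
#' (round half away from zero). Pyroglutamate and disulfides do not change
#' residue counts and are ignored.
#'
#' @param x One-letter amino-acid string or a [proteoform].
#' @param digits Decimal places of the reported percentage.
#' @return Percentage in `[0, 100]`.
#' @examples
#' hydrophobic_fraction(get_sequence("ABri", 1, 34))  # 38.2
#' @export
hydrophobic_fraction <- function(x, digits = 1) {
  if (inherits(x, "proteoform")) x <- get_sequence(x)
  aa <- strsplit(toupper(x), "")[[1]]
  if (length(aa) == 0) stop("empty sequence")
  unknown <- setdiff(aa, names(.AA_MONO))
  if (length(unknown))
    stop("unknown residue code(s): ", paste(unique(unknown), collapse = ", "))
  .round_half_up(100 * mean(aa %in% .HYDROPHOBIC), digits)
}

#' Truncation/modification subgroup labels of a proteoform
#'
#' Assigns the non-exclusive subgroup labels used for fractional-content
#' summaries: `full_length` (starts at 1, ends at the canonical C-terminus,
#' no pyroglutamate), `c_truncated` (ends before the canonical C-terminus),
#' `n_truncated` (starts after 1; by default an N-terminal pyroglutamate
#' also counts as an N-terminal modification), and `pyroglu`.
#'
#' @param species A [proteoform].
#' @param pyroglu_counts_n_truncated Should a position-1 pyroglutamate
#'   species count toward the N-truncated group? Default `TRUE`.
#' @return Character vector of labels.
#' @export
classify_subgroups <- function(species, pyroglu_counts_n_truncated = TRUE) {
  stopifnot(inherits(species, "proteoform"))
  cterm <- canonical_c_terminus(species$precursor)
  labels <- character(0)
  if (species$start == 1L && species$end == cterm && !species$pyroglu)
    labels <- c(labels, "full_length")
  if (species$end < cterm) labels <- c(labels, "c_truncated")
  if (species$start > 1L ||
      (species$pyroglu && isTRUE(pyroglu_counts_n_truncated)))
    labels <- c(labels, "n_truncated")
  if (species$pyroglu) labels <- c(labels, "pyroglu")
  labels
}

#' Convert a species-table row to a proteoform
#'
#' @param row One-row data frame with columns `precursor`, `start`, `end`,
#'   `pyroglu`, `disulfides` and optionally `display_name`.
#' @return A [proteoform].
#' @export
as_proteoform <- function(row) {
  proteoform(row$precursor, row$start, row$end, pyroglu = row$pyroglu,
             disulfides = row$disulfides,
             name = if ("display_name" %in% names(row)) row$display_name)
}

#' Read a proteoform species table
#'
#' CSV with columns `display_name, precursor, start, end, pyroglu,
#' disulfides`. Every row is validated through [proteoform()].
#'
#' @param path CSV file path.
#' @return Data frame with an added `mz` column (`[M+H]+`).
#' @export
read_species_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("display_name", "precursor", "start", "end", "pyroglu", "disulfides")
  if (!all(need %in% names(tab)))
    stop("species table must have columns: ", paste(need, collapse = ", "))
  tab$pyroglu <- as.logical(tab$pyroglu)
  tab$mz <- species_mz(tab)  # validates every row
  tab
}

#' Preset species tables for the three CAA cohorts
#'
#' Species lists for familial British dementia (8 ABri proteoforms),
#' familial Danish dementia (10 ADan plus 6 amyloid-beta proteoforms) and
#' sporadic CAA without AD (15 amyloid-beta proteoforms). The lists are
#' reconstructions consistent with the identified-peptide inventories of
#' the three cohorts (C-terminal variants x-34/x-29 for ABri;
#' x-34/x-33/x-29/x-28 for ADan; x-37/x-40/x-42 with N-terminal truncation
#' series for amyloid-beta; pyroglutamate and disulfide annotation
#' throughout).
#'
#' @param cohort `"FBD"`, `"FDD"` or `"CAA"`.
#' @return Species data frame (see [read_species_table]).
#' @export
species_preset <- function(cohort = c("FBD", "FDD", "CAA")) {
  cohort <- match.arg(cohort)
  file <- c(FBD = "species_fbd.csv", FDD = "species_fdd.csv",
            CAA = "species_caa.csv")[[cohort]]
  read_species_table(system.file("extdata", file, package = "vesselmap"))
}
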