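# Amino-acid lookups and bundled reference tables.
#
# All numeric reference data (random-coil shifts, CSI cutoffs, canonical
# beta-turn angles, hydropathy scale, generator emission model) ship as plain
# TSV under inst/extdata so they are versioned, inspectable and overridable
# without touching code.

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
AA1TO3 <- stats::setNames(names(AA3TO1), AA3TO1)

BACKBONE_ATOMS <- c("H", "HA", "HA2", "HA3", "N", "CA", "CB", "C")
CSI_NUCLEI <- c("HA", "CA", "CB", "C")
CHARGED_AA <- c("D", "E", "K", "R", "H")
TURN_TYPES <- c("I", "II", "I'", "II'", "VIII")

# atom-name aliases seen in the wild mapped to the canonical backbone set
ATOM_SYNONYMS <- c(CO = "C", "C'" = "C", HN = "H")

.ref_cache <- new.env(parent = emptyenv())

ref_path <- function(file) {
  p <- system.file("extdata", file, package = "nmrsecstr")
  if (!nzchar(p)) stop("bundled reference file not found: ", file)
  p
}

read_ref_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Random-coil reference chemical shifts
#'
#' Returns the residue-specific random-coil shift table used to compute
#' secondary shifts. The default table ships with the package (classic
#' CSI-era values); a user table with the same layout (columns `aa`, `H`,
#' `HA`, `CA`, `CB`, `C`, `N`) can be substituted.
#'
#' @param path Optional path to a replacement TSV table.
#' @return A numeric matrix with one-letter amino-acid codes as row names and
#'   atom names as column names. Glycine CB and proline H are `NA`.
#' @export
random_coil_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.ref_cache$rc)) return(.ref_cache$rc)
    path <- ref_path("random_coil_shifts.tsv")
    cache <- TRUE
  } else cache <- FALSE
  df <- read_ref_tsv(path)
  m <- as.matrix(df[, setdiff(names(df), "aa"), drop = FALSE])
  rownames(m) <- df$aa
  storage.mode(m) <- "double"
  if (cache) .ref_cache$rc <- m
  m
}

#' CSI digital-filter cutoffs
#'
#' Per-nucleus ppm cutoffs for the ternary filter: a secondary shift counts
#' as significant only when it strictly exceeds the cutoff in magnitude.
#'
#' @param path Optional replacement TSV (columns `atom`, `threshold`).
#' @return Named numeric vector over `HA`, `CA`, `CB`, `C`.
#' @export
csi_thresholds <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.ref_cache$thr)) return(.ref_cache$thr)
    path <- ref_path("csi_thresholds.tsv")
    cache <- TRUE
  } else cache <- FALSE
  df <- read_ref_tsv(path)
  v <- stats::setNames(as.numeric(df$threshold), df$atom)
  stopifnot(all(v > 0))
  if (cache) .ref_cache$thr <- v
  v
}

#' Canonical beta-turn torsion angles
#'
#' Characteristic (phi, psi) of the two central residues for turn types
#' I, II, I', II' and VIII.
#'
#' @param path Optional replacement TSV (columns `type`, `phi1`, `psi1`,
#'   `phi2`, `psi2`).
#' @return Numeric matrix, one row per turn type.
#' @export
canonical_turn_angles <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.ref_cache$turns)) return(.ref_cache$turns)
    path <- ref_path("turn_canonical_angles.tsv")
    cache <- TRUE
  } else cache <- FALSE
  df <- read_ref_tsv(path)
  m <- as.matrix(df[, c("phi1", "psi1", "phi2", "psi2")])
  rownames(m) <- df$type
  if (cache) .ref_cache$turns <- m
  m
}

kd_hydropathy <- function() {
  if (is.null(.ref_cache$kd)) {
    df <- read_ref_tsv(ref_path("hydropathy.tsv"))
    .ref_cache$kd <- stats::setNames(as.numeric(df$kd), df$aa)
  }
  .ref_cache$kd
}

is_hydrophobic <- function(aa) unname(kd_hydropathy()[aa] > 0)

generator_defaults <- function() {
  if (is.null(.ref_cache$gen)) {
    df <- read_ref_tsv(ref_path("generator_model.tsv"))
    .ref_cache$gen <- stats::setNames(as.numeric(df$value), df$key)
  }
  .ref_cache$gen
}

seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]
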