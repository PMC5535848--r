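#' Tryptic digestion parameters
#'
#' Parameter object for in-silico trypsin digestion. Trypsin cleaves
#' C-terminal to lysine (K) or arginine (R); when `proline_rule` is on,
#' cleavage is suppressed if the following residue is proline (P).
#'
#' Two conventions are in common use and both are exposed:
#' \describe{
#'   \item{search emulation}{up to 2 missed cleavages, peptide length >= 7,
#'     matching typical database-search settings;}
#'   \item{counting}{0 missed cleavages, length 7--30, the usual convention
#'     for theoretical-peptide-count ("possible peptides") normalization
#'     denominators (as in iBAQ-style normalization).}
#' }
#'
#' @param max_missed_cleavages Maximum number of internal cleavage sites a
#'   peptide may contain. Default 2.
#' @param min_peptide_length Minimum peptide length in residues. Default 7.
#' @param max_peptide_length Maximum peptide length in residues; `Inf` for
#'   unlimited. Default 30.
#' @param proline_rule Logical; suppress cleavage at K/R followed by P.
#'   Default `TRUE`.
#' @return An object of class `digest_params`.
#' @seealso [digest()], [count_theoretical_peptides()]
#' @export
digest_params <- function(max_missed_cleavages = 2L,
                          min_peptide_length = 7L,
                          max_peptide_length = 30,
                          proline_rule = TRUE) {
  max_missed_cleavages <- as.integer(max_missed_cleavages)
  min_peptide_length <- as.integer(min_peptide_length)
  if (is.na(max_missed_cleavages) || max_missed_cleavages < 0L)
    stop_("max_missed_cleavages must be a non-negative integer")
  if (is.na(min_peptide_length) || min_peptide_length < 1L)
    stop_("min_peptide_length must be a positive integer")
  if (!is.infinite(max_peptide_length))
    max_peptide_length <- as.integer(max_peptide_length)
  if (min_peptide_length > max_peptide_length)
    stop_("min_peptide_length must not exceed max_peptide_length")
  structure(list(max_missed_cleavages = max_missed_cleavages,
                 min_peptide_length = min_peptide_length,
                 max_peptide_length = max_peptide_length,
                 proline_rule = isTRUE(proline_rule)),
            class = "digest_params")
}

#' @export
print.digest_params <- function(x, ...) {
  cat("In-silico tryptic digest parameters\n")
  cat("  missed cleavages <= ", x$max_missed_cleavages, "\n", sep = "")
  cat("  peptide length in [", x$min_peptide_length, ", ",
      x$max_peptide_length, "]\n", sep = "")
  cat("  proline rule: ", if (x$proline_rule) "on" else "off", "\n", sep = "")
  invisible(x)
}

# Positions (1-based) after which trypsin cleaves.
cleavage_sites <- function(residues, proline_rule) {
  n <- length(residues)
  if (n == 0L) return(integer(0))
  kr <- which(residues == "K" | residues == "R")
  kr <- kr[kr < n]  # the C-terminus is a boundary, not a cleavage site
  if (proline_rule && length(kr)) kr <- kr[residues[kr + 1L] != "P"]
  kr
}

#' In-silico tryptic digestion of one protein sequence
#'
#' Enumerates the tryptic peptides of an amino-acid sequence: cleavage after
#' K or R (suppressed before P when the proline rule is on), keeping every
#' peptide with at most `max_missed_cleavages` internal cleavage sites and a
#' length within the configured bounds. Peptides arising from repeated
#' subsequences are kept as distinct positional peptides.
#'
#' @param sequence A single amino-acid string over the 20-letter alphabet.
#' @param params A [digest_params()] object.
#' @return Character vector of peptides, ordered by start position then
#'   number of missed cleavages. An empty sequence yields `character(0)`.
#' @examples
#' digest("MKWVTFISLLFLFSSAYSR", digest_params(max_missed_cleavages = 0))
#' @export
digest <- function(sequence, params = digest_params()) {
  stopifnot(inherits(params, "digest_params"))
  if (length(sequence) != 1L || !is.character(sequence))
    stop_("sequence must be a single character string")
  if (nchar(sequence) == 0L) return(character(0))
  residues <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  bad <- which(!(residues %in% AA_ALPHABET20))
  if (length(bad))
    stop_("illegal residue '", residues[bad[1]], "' at position ", bad[1])
  n <- length(residues)
  # boundaries: 0, each cleavage site, and the C-terminus
  bounds <- unique(c(0L, cleavage_sites(residues, params$proline_rule), n))
  nb <- length(bounds)
  out <- character(0)
  for (i in seq_len(nb - 1L)) {
    jmax <- min(nb, i + 1L + params$max_missed_cleavages)
    for (j in (i + 1L):jmax) {
      len <- bounds[j] - bounds[i]
      if (len >= params$min_peptide_length && len <= params$max_peptide_length)
        out <- c(out, substr(sequence, bounds[i] + 1L, bounds[j]))
    }
  }
  out
}

#' Theoretical peptide counts for a set of proteins
#'
#' Counts the in-silico tryptic peptides of each protein, used as the
#' per-protein denominator in peptide-count normalization of precursor
#' areas. The default `"counting"` mode uses 0 missed cleavages and lengths
#' 7--30 (the conventional "possible peptides" definition); `"search"` mode
#' uses the search-emulation settings (<= 2 missed cleavages, length >= 7).
#' Supplying `params` overrides either mode.
#'
#' @param proteome Named character vector of amino-acid sequences; names are
#'   accessions.
#' @param params Optional [digest_params()]; overrides `mode`.
#' @param mode `"counting"` (default) or `"search"`.
#' @return Data frame with columns `accession`, `n_theoretical_peptides`,
#'   and logical `zero_peptides` flagging proteins that yield no peptide
#'   (these cannot be peptide-count normalized and are dropped downstream).
#' @export
count_theoretical_peptides <- function(proteome, params = NULL,
                                       mode = c("counting", "search")) {
  if (length(proteome) == 0L) stop_("proteome must be nonempty")
  acc <- names(proteome)
  if (is.null(acc) || any(!nzchar(acc)))
    stop_("proteome sequences must be named by accession")
  if (anyDuplicated(acc))
    stop_("duplicate accession(s): ",
          paste(unique(acc[duplicated(acc)]), collapse = ", "))
  if (is.null(params)) {
    mode <- match.arg(mode)
    params <- if (mode == "counting") {
      digest_params(max_missed_cleavages = 0L, min_peptide_length = 7L,
                    max_peptide_length = 30L)
    } else {
      digest_params(max_missed_cleavages = 2L, min_peptide_length = 7L,
                    max_peptide_length = Inf)
    }
  }
  counts <- vapply(proteome, function(s) length(digest(s, params)), integer(1))
  data.frame(accession = acc,
             n_theoretical_peptides = unname(counts),
             zero_peptides = unname(counts) == 0L,
             stringsAsFactors = FALSE)
}
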