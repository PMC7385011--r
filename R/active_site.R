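#' Parse a residue list in one-letter notation
#'
#' Parses text such as `"L60, Q64, A67"` (one-letter amino-acid code
#' followed by the author residue number, comma- or whitespace-separated)
#' into a residue set. Duplicate residue numbers are rejected.
#'
#' @param text character scalar, or vector of tokens.
#' @param provenance label recording how the set was obtained: `"Dock"`
#'   (energetically favourable in docking), `"CvG"` (lining cavities and
#'   grooves), `"IS"` (interaction-surface member) or `"Combined"`.
#' @return An object of class `residue_set`: data.frame `members` with
#'   columns `res_id`, `aa`, plus the `provenance` label.
#' @export
parse_residue_list <- function(text, provenance = c("Dock", "CvG", "IS",
                                                    "Combined")) {
  provenance <- match.arg(provenance)
  tokens <- if (length(text) == 1L)
    strsplit(trimws(text), "[,[:space:]]+")[[1]] else text
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens)) stop("empty residue list")
  m <- regmatches(tokens, regexec("^([A-Za-z])([0-9]+)$", tokens))
  bad <- which(vapply(m, length, integer(1)) != 3L)
  if (length(bad))
    stop(sprintf("parse error at token %d: malformed entry '%s'",
                 bad[1L], tokens[bad[1L]]))
  aa <- toupper(vapply(m, `[[`, character(1), 2L))
  res_id <- as.integer(vapply(m, `[[`, character(1), 3L))
  invalid <- which(!aa %in% VALID_AA)
  if (length(invalid))
    stop(sprintf("parse error at token %d: invalid amino-acid code '%s'",
                 invalid[1L], aa[invalid[1L]]))
  if (anyDuplicated(res_id))
    stop("duplicate residue number: ", res_id[duplicated(res_id)][1L])
  residue_set(res_id, aa, provenance)
}

#' Construct a residue set
#'
#' @param res_id integer residue numbers (unique).
#' @param aa one-letter amino-acid codes.
#' @param provenance see [parse_residue_list()].
#' @return A `residue_set`.
#' @export
residue_set <- function(res_id, aa, provenance = "Combined") {
  stopifnot(length(res_id) == length(aa))
  if (anyDuplicated(res_id)) stop("res_ids must be unique")
  if (any(!aa %in% VALID_AA)) stop("invalid amino-acid code")
  ord <- order(res_id)
  structure(list(members = data.frame(res_id = as.integer(res_id[ord]),
                                      aa = as.character(aa[ord])),
                 provenance = provenance),
            class = "residue_set")
}

#' @export
print.residue_set <- function(x, ...) {
  cat(sprintf("<residue_set> %s: %d residues (%s%s)\n", x$provenance,
              nrow(x$members),
              paste(head(paste0(x$members$aa, x$members$res_id), 6),
                    collapse = ", "),
              if (nrow(x$members) > 6) ", ..." else ""))
  invisible(x)
}

#' @export
length.residue_set <- function(x) nrow(x$members)

#' Combine docking-favourable and cavity-lining residue sets
#'
#' The putative active-site residue set is the intersection of the
#' docking-favourable set and the cavity/groove-lining set,
#' AA = AA^Dock intersect AA^CvG. The expectation that this combined set is
#' contained in the interaction-surface set AA^IS is checked and reported
#' (violations are flagged in the `not_in_is` attribute, never filtered
#' out).
#'
#' @param dock,cvg,is_ `residue_set` objects.
#' @return A `residue_set` (provenance `"Combined"`) with attribute
#'   `not_in_is`: data.frame of members absent from `is_`.
#' @export
combine_active_site <- function(dock, cvg, is_) {
  key <- function(rs) paste0(rs$members$aa, rs$members$res_id)
  shared <- intersect(key(dock), key(cvg))
  sel <- dock$members[key(dock) %in% shared, , drop = FALSE]
  out <- residue_set(sel$res_id, sel$aa, "Combined")
  flags <- out$members[!paste0(out$members$aa, out$members$res_id) %in%
                         key(is_), , drop = FALSE]
  attr(out, "not_in_is") <- flags
  out
}

## Amino-acid classes used for groove composition profiling. Disjoint by
## construction: S and T count in ST only; the catalytic-propensity class
## CAT is tracked to verify the exclusion of E, C and H from active-site
## sets. G is untracked.
AA_CLASSES <- list(
  AAA  = c("W", "F", "Y"),
  P    = "P",
  RKNQ = c("R", "K", "N", "Q"),
  ST   = c("S", "T"),
  HSC  = c("L", "I", "V", "A", "M"),
  CAT  = c("D", "E", "C", "H")
)

#' Amino-acid class composition of a residue set
#'
#' Fractions of the set falling into the classes relevant to a
#' cellulose-binding groove: aromatics AAA = {W,F,Y} (stacking against
#' glucopyranose rings), proline P, electrostatic stabilisers
#' RKNQ = {R,K,N,Q}, hydroxyl pair ST = {S,T}, short hydrophobic side
#' chains HSC = {L,I,V,A,M}, and the catalytic-propensity class
#' CAT = {D,E,C,H} whose absence distinguishes a binding groove from a
#' catalytic site. Classes are disjoint; glycine is untracked, so the six
#' fractions sum to at most 1.
#'
#' @param rs a `residue_set`.
#' @return An object of class `composition_stats`: named `fractions`,
#'   named `counts` and `total`.
#' @export
composition <- function(rs) {
  stopifnot(inherits(rs, "residue_set"))
  n <- nrow(rs$members)
  if (n == 0L) stop("precondition error: empty residue set")
  counts <- vapply(AA_CLASSES, function(cl) sum(rs$members$aa %in% cl),
                   integer(1))
  structure(list(fractions = counts / n, counts = counts, total = n),
            class = "composition_stats")
}

#' @export
print.composition_stats <- function(x, ...) {
  cat(sprintf("<composition_stats> n = %d\n", x$total))
  for (k in names(x$fractions))
    cat(sprintf("  %-5s %2d/%d = %5.1f%%\n", k, x$counts[k], x$total,
                100 * x$fractions[k]))
  invisible(x)
}

#' Published contact-residue lists of the characterized class C enzymes
#'
#' The residues of the four characterized enzymes found to interact with
#' cello-oligosaccharide ligands (union of the docking-favourable and
#' cavity/groove-lining sets; the published rendering distinguishes the
#' subsets typographically, which plain text cannot recover, so the lists
#' are ingested as the union).
#'
#' @return Named list of `residue_set` objects (UniProt accessions as
#'   names), provenance `"Dock"`.
#' @export
active_site_table <- function() {
  tab <- read.delim(system.file("extdata", "active_site_residues.tsv",
                                package = "clefscope"),
                    stringsAsFactors = FALSE)
  out <- lapply(tab$residues, parse_residue_list, provenance = "Dock")
  names(out) <- tab$id
  out
}
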