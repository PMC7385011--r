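#' @importFrom stats cov dist prcomp rnorm runif sd setNames wilcox.test
#' @importFrom utils head read.delim write.table packageVersion
NULL

VALID_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Construct a C-alpha structure
#'
#' A `ca_structure` holds one entry per residue bearing a C-alpha atom:
#' chain identifier, author residue number, one-letter amino-acid code and
#' the C-alpha coordinate in Angstrom. It is the common currency of all
#' downstream analyses (superposition, elastic-network modes, grooves).
#'
#' @param chain character vector of chain identifiers.
#' @param res_id integer vector of author residue numbers.
#' @param aa character vector of one-letter amino-acid codes.
#' @param xyz numeric N x 3 matrix of coordinates (Angstrom).
#' @param name text label for the structure.
#' @return An object of class `ca_structure` with fields `chain`, `res_id`,
#'   `aa`, `xyz` and `name`.
#' @export
ca_structure <- function(chain, res_id, aa, xyz, name = "structure") {
  xyz <- as.matrix(xyz)
  n <- length(res_id)
  if (n < 1L) stop("a structure must contain at least one residue")
  if (length(chain) == 1L) chain <- rep(chain, n)
  stopifnot(length(chain) == n, length(aa) == n,
            nrow(xyz) == n, ncol(xyz) == 3L)
  if (!all(is.finite(xyz))) stop("all coordinates must be finite")
  key <- paste(chain, res_id)
  if (anyDuplicated(key))
    stop("duplicate (chain, res_id) pair: ", key[duplicated(key)][1L])
  bad <- !aa %in% VALID_AA
  if (any(bad))
    stop("invalid one-letter amino-acid code: ", aa[bad][1L])
  structure(list(chain = as.character(chain),
                 res_id = as.integer(res_id),
                 aa = as.character(aa),
                 xyz = unname(xyz),
                 name = as.character(name)),
            class = "ca_structure")
}

#' @export
print.ca_structure <- function(x, ...) {
  cat(sprintf("<ca_structure> %s: %d residues, chains %s\n",
              x$name, length(x$res_id),
              paste(unique(x$chain), collapse = ",")))
  invisible(x)
}

#' @export
length.ca_structure <- function(x) length(x$res_id)

#' Subset a structure by residue index
#'
#' @param s a `ca_structure`.
#' @param idx integer positions (1-based, in file order) to keep.
#' @return A `ca_structure` containing the selected residues.
#' @export
structure_subset <- function(s, idx) {
  ca_structure(s$chain[idx], s$res_id[idx], s$aa[idx],
               s$xyz[idx, , drop = FALSE], name = s$name)
}

#' Read a C-alpha structure from a PDB file
#'
#' Parses ATOM records (via bio3d) and keeps one entry per residue bearing a
#' CA atom, in file order. Alternate locations are resolved to the highest
#' occupancy, first-listed on ties. Insertion codes are rejected: homology
#' models do not carry them and silently merging them would be ambiguous.
#'
#' @param path PDB file path.
#' @param chain optional chain identifier to restrict to.
#' @param name label for the structure; defaults to the file base name.
#' @return A [ca_structure()].
#' @export
read_structure <- function(path, chain = NULL, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE))
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!is.null(chain)) atoms <- atoms[atoms$chain %in% chain, , drop = FALSE]
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) stop("format error: no CA atoms in ", path)
  if (any(!is.na(ca$insert) & ca$insert != ""))
    stop("insertion codes are not supported (found in ", path, ")")
  ## altloc: keep highest occupancy, then first-listed
  key <- paste(ca$chain, ca$resno)
  occ <- ifelse(is.na(ca$o), 1, ca$o)
  keep <- rep(TRUE, nrow(ca))
  for (k in unique(key[duplicated(key)])) {
    i <- which(key == k)
    best <- i[which.max(occ[i])]
    keep[setdiff(i, best)] <- FALSE
  }
  ca <- ca[keep, , drop = FALSE]
  key <- paste(ca$chain, ca$resno)
  if (anyDuplicated(key))
    stop("integrity error: duplicate residue after altloc resolution: ",
         key[duplicated(key)][1L])
  aa1 <- bio3d::aa321(ca$resid)
  if (any(is.na(aa1) | aa1 == "X"))
    stop("unknown residue type: ", ca$resid[is.na(aa1) | aa1 == "X"][1L])
  ch <- ifelse(is.na(ca$chain) | ca$chain == "", "A", ca$chain)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  ca_structure(ch, ca$resno, aa1, cbind(ca$x, ca$y, ca$z), name = name)
}

#' Write a C-alpha structure to a PDB file
#'
#' Emits one CA ATOM record per residue (coordinates to 3 decimals, element
#' column "C"), a TER record and END.
#'
#' @param s a [ca_structure()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "ca_structure"))
  if (any(s$res_id > 9999L | s$res_id < -999L))
    stop("serialization error: residue number outside PDB field width: ",
         s$res_id[which(s$res_id > 9999L | s$res_id < -999L)[1L]])
  n <- length(s$res_id)
  aa3 <- bio3d::aa123(s$aa)
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(s$xyz)),
                   type = rep("ATOM", n), resno = s$res_id, resid = aa3,
                   chain = s$chain, elety = rep("CA", n),
                   o = rep(1.00, n), b = rep(0.00, n),
                   elesy = rep("C", n), end = TRUE)
  invisible(path)
}

#' Write a multi-model (ensemble) PDB file
#'
#' @param structures list of [ca_structure()] objects with identical residue
#'   tables.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(structures, path) {
  stopifnot(length(structures) >= 1L)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(structures)) {
    s <- structures[[m]]
    writeLines(sprintf("MODEL     %4d", m), con)
    aa3 <- bio3d::aa123(s$aa)
    lines <- sprintf(
      "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_along(s$res_id), aa3, s$chain, s$res_id,
      s$xyz[, 1], s$xyz[, 2], s$xyz[, 3])
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Domain architecture annotation
#'
#' Class C GH9 endoglucanases comprise a catalytic GH9 domain, a linker (L)
#' and a CBM49 carbohydrate-binding module. An annotation maps each domain
#' label to one or more inclusive author residue-number ranges.
#'
#' @param intervals named list; names from `{"GH9","L","CBM49"}`, each element
#'   a 2-column matrix (or vector of length 2) of inclusive `res_id` ranges.
#' @param s optional [ca_structure()]; if given, every annotated residue is
#'   checked to exist in it.
#' @return An object of class `domain_annotation`.
#' @export
domain_annotation <- function(intervals, s = NULL) {
  labs <- names(intervals)
  if (is.null(labs) || !all(labs %in% c("GH9", "L", "CBM49")))
    stop("domain labels must be among GH9, L, CBM49")
  intervals <- lapply(intervals, function(x) {
    m <- matrix(as.integer(x), ncol = 2, byrow = is.null(dim(x)))
    if (any(m[, 1] > m[, 2])) stop("interval start exceeds end")
    m
  })
  ids <- lapply(intervals, function(m)
    unlist(lapply(seq_len(nrow(m)), function(i) m[i, 1]:m[i, 2])))
  for (lab in labs)
    if (anyDuplicated(ids[[lab]]))
      stop("overlapping ranges within domain ", lab)
  all_ids <- unlist(ids)
  if (anyDuplicated(all_ids))
    stop("domains must be mutually disjoint; res_id ",
         all_ids[duplicated(all_ids)][1L], " is annotated twice")
  if (!is.null(s)) {
    missing <- setdiff(all_ids, s$res_id)
    if (length(missing))
      stop("annotated res_id not present in structure: ", missing[1L])
  }
  structure(list(intervals = intervals), class = "domain_annotation")
}

#' Look up the domain label of residues
#'
#' @param dom a [domain_annotation()].
#' @param res_id integer vector of author residue numbers.
#' @return Character vector of labels (`NA` where unannotated).
#' @export
domain_of <- function(dom, res_id) {
  stopifnot(inherits(dom, "domain_annotation"))
  out <- rep(NA_character_, length(res_id))
  for (lab in names(dom$intervals)) {
    m <- dom$intervals[[lab]]
    for (i in seq_len(nrow(m)))
      out[res_id >= m[i, 1] & res_id <= m[i, 2]] <- lab
  }
  out
}

#' Read domain annotations from a YAML config
#'
#' Expects `domains: {GH9: [[a,b]], L: [[c,d]], CBM49: [[e,f]]}`.
#'
#' @param path YAML file path.
#' @param s optional [ca_structure()] for validation.
#' @return A [domain_annotation()].
#' @export
read_domains_yaml <- function(path, s = NULL) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$domains)) stop("YAML config lacks a 'domains' key")
  iv <- lapply(cfg$domains, function(rr)
    do.call(rbind, lapply(rr, function(ab) as.integer(ab))))
  domain_annotation(iv, s = s)
}

#' Read a multiple sequence alignment and map columns to residues
#'
#' Accepts FASTA or Clustal alignments ("-" and "." are both gaps). Each
#' ungapped MSA sequence must equal the concatenated amino-acid string of its
#' structure; sequences are matched to structures by name when all structure
#' names occur in the MSA, otherwise by order.
#'
#' @param path alignment file (FASTA or Clustal).
#' @param structures list of [ca_structure()] objects.
#' @return An object of class `alignment_map` with fields `n_columns`,
#'   `maps` (per structure, integer vector of `res_id` per column, `NA` at
#'   gaps), `ungapped_columns` (1-based columns occupied in all sequences)
#'   and `names`.
#' @export
read_alignment <- function(path, structures) {
  first <- readLines(path, n = 1L)
  if (grepl("^CLUSTAL", first, ignore.case = TRUE)) {
    seqs <- read_clustal(path)
  } else {
    aln <- seqinr::read.alignment(path, format = "fasta",
                                  forceToLower = FALSE)
    seqs <- toupper(vapply(aln$seq, function(x) gsub("[[:space:]]", "", x),
                           character(1)))
    names(seqs) <- aln$nam
  }
  alignment_map_from_strings(seqs, structures)
}

## Minimal Clustal block reader: header line, then blocks of
## "<name> <chunk> [count]" lines separated by blank/conservation lines.
read_clustal <- function(path) {
  lines <- readLines(path)[-1]
  pat <- "^(\\S+)\\s+([A-Za-z.\\-]+)\\s*[0-9]*\\s*$"
  hits <- grepl(pat, lines)
  nm <- sub(pat, "\\1", lines[hits])
  chunk <- sub(pat, "\\2", lines[hits])
  if (!length(nm)) stop("no sequence lines found in Clustal file ", path)
  out <- vapply(unique(nm),
                function(x) paste(chunk[nm == x], collapse = ""),
                character(1))
  toupper(out)
}

#' Build an alignment map from in-memory aligned strings
#'
#' @param seqs named character vector of aligned sequences (equal lengths;
#'   `-` or `.` for gaps).
#' @param structures list of [ca_structure()] objects, one per sequence.
#' @return An `alignment_map`; see [read_alignment()].
#' @export
alignment_map_from_strings <- function(seqs, structures) {
  stopifnot(length(seqs) == length(structures))
  widths <- unique(nchar(seqs))
  if (length(widths) != 1L) stop("aligned sequences differ in length")
  n_col <- widths
  snames <- vapply(structures, function(s) s$name, character(1))
  ord <- seq_along(structures)
  if (!is.null(names(seqs)) && all(snames %in% names(seqs)) &&
      !anyDuplicated(names(seqs)))
    ord <- match(snames, names(seqs))
  maps <- vector("list", length(structures))
  for (i in seq_along(structures)) {
    s <- structures[[i]]
    chars <- strsplit(seqs[[ord[i]]], "")[[1]]
    occupied <- !(chars %in% c("-", "."))
    res_seq <- chars[occupied]
    if (length(res_seq) != length(s$aa))
      stop(sprintf(
        "mapping error for %s: alignment has %d residues, structure has %d",
        s$name, length(res_seq), length(s$aa)))
    mism <- which(res_seq != s$aa)
    if (length(mism))
      stop(sprintf(
        "mapping error for %s: first discordant position %d (MSA %s vs structure %s)",
        s$name, mism[1L], res_seq[mism[1L]], s$aa[mism[1L]]))
    v <- rep(NA_integer_, n_col)
    v[occupied] <- s$res_id
    maps[[i]] <- v
  }
  occ <- vapply(maps, function(v) !is.na(v), logical(n_col))
  if (n_col == 1L) occ <- matrix(occ, nrow = 1L)
  structure(list(n_columns = n_col,
                 maps = setNames(maps, snames),
                 ungapped_columns = which(rowSums(occ) == length(maps)),
                 names = snames),
            class = "alignment_map")
}

#' @export
print.alignment_map <- function(x, ...) {
  cat(sprintf("<alignment_map> %d sequences, %d columns, %d ungapped\n",
              length(x$maps), x$n_columns, length(x$ungapped_columns)))
  invisible(x)
}

#' Corrected full-length subset matched to a truncated structure
#'
#' Truncation experiments compare a full-length enzyme against its
#' GH9+linker-only form. For a like-for-like comparison the full-length model
#' is reduced to its residues at alignment columns occupied by both
#' sequences: x_cFL = x_FL - (x_FL - x_T) as a set of matched residues.
#'
#' @param full full-length [ca_structure()].
#' @param truncated truncated [ca_structure()].
#' @param map an `alignment_map` containing both structures.
#' @return A [ca_structure()] holding the residues of `full` at shared
#'   columns (length = number of shared columns).
#' @export
corrected_subset <- function(full, truncated, map) {
  stopifnot(inherits(map, "alignment_map"))
  for (nm in c(full$name, truncated$name))
    if (!nm %in% map$names)
      stop("structure ", nm, " is not present in the alignment map")
  vf <- map$maps[[full$name]]
  vt <- map$maps[[truncated$name]]
  shared <- which(!is.na(vf) & !is.na(vt))
  if (!length(shared))
    stop("empty-result error: the two sequences share no alignment columns")
  idx <- match(vf[shared], full$res_id)
  out <- structure_subset(full, idx)
  out$name <- paste0(full$name, "_corrected")
  out
}
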