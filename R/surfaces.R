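#' Detect correlated residue segment pairs in a cross-correlation map
#'
#' Scans a DCCM for maximal rectangular blocks of strong positive
#' correlation between sequence-distant residues: a block is a pair of
#' residue runs (I, J), each at least `min_len` long and confined to one
#' annotated domain, with every entry C[I, J] >= r_min and every residue
#' pair at least `min_separation` apart in sequence, that cannot be extended
#' in any direction without breaking one of these conditions. Such blocks
#' are the footprints of inter-segment interaction surfaces.
#'
#' @param C a `correlation_map` (or plain N x N matrix).
#' @param domains a [domain_annotation()] covering the residues.
#' @param res_id residue numbers behind the matrix rows (default `1:N` or
#'   the map labels if numeric).
#' @param r_min correlation threshold in (0, 1] (default 0.8).
#' @param min_len minimum run length in residues (default 4).
#' @param min_separation minimum sequence separation between paired
#'   residues (default 10).
#' @return data.frame of segment pairs: `a_start`, `a_end`, `a_domain`,
#'   `b_start`, `b_end`, `b_domain` (author residue numbers, inclusive) and
#'   `mean_r`. Sublabels (G1..Gk / C1..Ck / L) are added by
#'   [label_segments()].
#' @export
correlated_segments <- function(C, domains, res_id = NULL, r_min = 0.8,
                                min_len = 4L, min_separation = 10L) {
  M <- if (inherits(C, "correlation_map")) C$matrix else as.matrix(C)
  n <- nrow(M)
  if (is.null(res_id)) {
    labs <- if (inherits(C, "correlation_map")) C$labels else NULL
    res_id <- if (!is.null(labs) && !anyNA(suppressWarnings(as.integer(labs))))
      as.integer(labs) else seq_len(n)
  }
  stopifnot(r_min > 0, r_min <= 1, min_len >= 2L, length(res_id) == n)
  dom <- domain_of(domains, res_id)
  ## candidate index intervals: maximal domain-pure runs of consecutive rows
  runs <- domain_runs(dom)
  out <- list()
  B0 <- M >= r_min
  for (ra in seq_len(nrow(runs))) for (rb in seq_len(nrow(runs))) {
    ia <- runs$from[ra]:runs$to[ra]
    ib <- runs$from[rb]:runs$to[rb]
    if (length(ia) < min_len || length(ib) < min_len) next
    if (ra > rb) next   # report each unordered pair once (upper orientation)
    B <- B0[ia, ib, drop = FALSE] &
      abs(outer(ia, ib, "-")) >= min_separation
    recs <- maximal_true_blocks(B, min_len)
    if (!nrow(recs)) next
    for (k in seq_len(nrow(recs))) {
      I <- ia[recs$r1[k]:recs$r2[k]]; J <- ib[recs$c1[k]:recs$c2[k]]
      if (ra == rb && I[1] > J[1]) next      # same-run mirror duplicate
      out[[length(out) + 1L]] <- data.frame(
        a_start = res_id[I[1]], a_end = res_id[I[length(I)]],
        a_domain = dom[I[1]],
        b_start = res_id[J[1]], b_end = res_id[J[length(J)]],
        b_domain = dom[J[1]],
        mean_r = mean(M[I, J]))
    }
  }
  if (!length(out))
    return(data.frame(a_start = integer(0), a_end = integer(0),
                      a_domain = character(0), b_start = integer(0),
                      b_end = integer(0), b_domain = character(0),
                      mean_r = numeric(0)))
  res <- do.call(rbind, out)
  res[order(res$a_start, res$b_start), , drop = FALSE]
}

domain_runs <- function(dom) {
  n <- length(dom)
  keep <- !is.na(dom)
  brk <- c(TRUE, dom[-1] != dom[-n] | is.na(dom[-1]) != is.na(dom[-n]))
  id <- cumsum(brk)
  from <- tapply(seq_len(n), id, min)
  to <- tapply(seq_len(n), id, max)
  ok <- keep[from]
  data.frame(from = as.integer(from[ok]), to = as.integer(to[ok]))
}

## All maximal all-TRUE rectangles of B with both sides >= min_len.
## Row intervals are enumerated with column-cumulative sums; a rectangle is
## kept only if no single-row or single-column extension stays all-TRUE.
maximal_true_blocks <- function(B, min_len) {
  m <- nrow(B); p <- ncol(B)
  empty <- data.frame(r1 = integer(0), r2 = integer(0),
                      c1 = integer(0), c2 = integer(0))
  if (m < min_len || p < min_len || !any(B)) return(empty)
  S <- apply(B, 2, cumsum)
  rs <- rowSums(B)
  out <- list()
  for (r1 in seq_len(m - min_len + 1L)) {
    if (rs[r1] < min_len) next
    for (r2 in seq(r1 + min_len - 1L, m)) {
      tot <- if (r1 > 1L) S[r2, ] - S[r1 - 1L, ] else S[r2, ]
      col_ok <- tot == (r2 - r1 + 1L)
      if (!any(col_ok)) break       # monotone: larger r2 cannot recover
      rl <- rle(col_ok)
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1L
      for (q in which(rl$values & rl$lengths >= min_len)) {
        c1 <- starts[q]; c2 <- ends[q]
        ## maximality in rows: extending up or down must break some column
        if (r1 > 1L && all(B[r1 - 1L, c1:c2])) next
        if (r2 < m && all(B[r2 + 1L, c1:c2])) next
        out[[length(out) + 1L]] <- c(r1, r2, c1, c2)
      }
    }
  }
  if (!length(out)) return(empty)
  rec <- unique(do.call(rbind, out))
  data.frame(r1 = rec[, 1], r2 = rec[, 2], c1 = rec[, 3], c2 = rec[, 4])
}

#' Assign sublabels to the segments of a pair list
#'
#' Segments confined to GH9 are labelled G1..Gk, CBM49 segments C1..Ck and
#' linker segments L (L1..Lk if several), by ascending start position.
#'
#' @param pairs output of [correlated_segments()].
#' @return `pairs` with added `a_label` / `b_label` columns.
#' @export
label_segments <- function(pairs) {
  segs <- unique(rbind(
    data.frame(start = pairs$a_start, end = pairs$a_end, dom = pairs$a_domain),
    data.frame(start = pairs$b_start, end = pairs$b_end, dom = pairs$b_domain)))
  segs <- segs[order(segs$start, segs$end), , drop = FALSE]
  prefix <- c(GH9 = "G", L = "L", CBM49 = "C")[segs$dom]
  lab <- character(nrow(segs))
  for (d in unique(segs$dom)) {
    i <- which(segs$dom == d)
    lab[i] <- if (d == "L" && length(i) == 1L) "L"
              else paste0(prefix[i], seq_along(i))
  }
  segs$label <- lab
  key <- function(s, e, d) paste(s, e, d)
  sk <- key(segs$start, segs$end, segs$dom)
  pairs$a_label <- segs$label[match(key(pairs$a_start, pairs$a_end,
                                        pairs$a_domain), sk)]
  pairs$b_label <- segs$label[match(key(pairs$b_start, pairs$b_end,
                                        pairs$b_domain), sk)]
  pairs
}

#' Classify inter-domain interaction surfaces
#'
#' Segment pairs are grouped into connected components (segments sharing a
#' residue interval are one node; each pair is an edge). A component whose
#' segments span two domains is an interaction surface of class GC, GL or
#' CL; a component touching GH9, linker and CBM49 is the three-way class
#' GLC. When a structure is supplied, the buried surface area between the
#' two domain sides of each surface is computed with
#' [buried_interface_area()].
#'
#' @param pairs labelled segment pairs ([correlated_segments()], optionally
#'   through [label_segments()]).
#' @param domains a [domain_annotation()].
#' @param s optional [ca_structure()] for buried-area quantification.
#' @param probe probe radius in Angstrom (default 1.4).
#' @param radius per-residue sphere radius in Angstrom (default 3.0).
#' @return data.frame with one row per surface: `class`, `n_pairs`,
#'   `segments`, `mean_r` and `buried_area_A2` (NA without a structure).
#' @export
classify_surfaces <- function(pairs, domains, s = NULL, probe = 1.4,
                              radius = 3.0) {
  if (!nrow(pairs))
    return(data.frame(class = character(0), n_pairs = integer(0),
                      segments = character(0), mean_r = numeric(0),
                      buried_area_A2 = numeric(0)))
  if (anyNA(pairs$a_domain) || anyNA(pairs$b_domain))
    stop("annotation error: segment with unannotated residues")
  if (is.null(pairs$a_label)) pairs <- label_segments(pairs)
  seg_key <- unique(c(paste(pairs$a_start, pairs$a_end),
                      paste(pairs$b_start, pairs$b_end)))
  comp <- seq_along(seg_key)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (k in seq_len(nrow(pairs))) {
    i <- find(match(paste(pairs$a_start[k], pairs$a_end[k]), seg_key))
    j <- find(match(paste(pairs$b_start[k], pairs$b_end[k]), seg_key))
    comp[max(i, j)] <- min(i, j)
  }
  roots <- vapply(seq_along(seg_key), find, integer(1))
  pair_root <- roots[match(paste(pairs$a_start, pairs$a_end), seg_key)]
  out <- lapply(unique(pair_root), function(rt) {
    pp <- pairs[pair_root == rt, , drop = FALSE]
    doms <- sort(unique(c(pp$a_domain, pp$b_domain)))
    cls <- if (setequal(doms, c("GH9", "L", "CBM49"))) "GLC"
      else if (setequal(doms, c("GH9", "CBM49"))) "GC"
      else if (setequal(doms, c("GH9", "L"))) "GL"
      else if (setequal(doms, c("CBM49", "L"))) "CL"
      else paste(doms, collapse = "")
    segtxt <- paste(sort(unique(c(
      sprintf("%s:%d-%d", pp$a_label, pp$a_start, pp$a_end),
      sprintf("%s:%d-%d", pp$b_label, pp$b_start, pp$b_end)))),
      collapse = ";")
    bsa <- NA_real_
    if (!is.null(s)) {
      ia <- unique(unlist(mapply(seq, pp$a_start, pp$a_end,
                                 SIMPLIFY = FALSE)))
      ib <- unique(unlist(mapply(seq, pp$b_start, pp$b_end,
                                 SIMPLIFY = FALSE)))
      ib <- setdiff(ib, ia)
      bsa <- buried_interface_area(s, ia, ib, probe = probe, radius = radius)
    }
    data.frame(class = cls, n_pairs = nrow(pp), segments = segtxt,
               mean_r = mean(pp$mean_r), buried_area_A2 = bsa)
  })
  do.call(rbind, out)
}

## Deterministic golden-section spiral point set on the unit sphere.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe over a sphere model of the structure: each residue is a
#' sphere centred on its C-alpha (default radius 3.0 Angstrom, approximating
#' side-chain extent in C-alpha-only models). Quadrature points on each
#' probe-inflated sphere are tested against all neighbouring inflated
#' spheres; the accessible fraction times the inflated-sphere area gives the
#' per-residue SASA. The point set is a deterministic golden-section spiral.
#'
#' @param s a [ca_structure()] or N x 3 coordinate matrix.
#' @param radius per-residue sphere radius, scalar or length-N (Angstrom).
#' @param probe probe radius in Angstrom (default 1.4).
#' @param n_points quadrature points per sphere (>= 92; default 960).
#' @param subset optional indices: only these residues' areas are computed
#'   (occlusion still uses all residues).
#' @return Numeric vector of per-residue SASA in square Angstrom.
#' @export
shrake_rupley_sasa <- function(s, radius = 3.0, probe = 1.4,
                               n_points = 960L, subset = NULL) {
  xyz <- if (inherits(s, "ca_structure")) s$xyz else as.matrix(s)
  n <- nrow(xyz)
  if (length(radius) == 1L) radius <- rep(radius, n)
  stopifnot(length(radius) == n, all(radius > 0), n_points >= 92L)
  if (n > 1L && min(dist(xyz)) < 1e-9)
    stop("geometry error: coincident sphere centers")
  R <- radius + probe
  pts <- sphere_points(n_points)
  if (is.null(subset)) subset <- seq_len(n)
  area <- numeric(length(subset))
  d2all <- as.matrix(dist(xyz))^2
  for (k in seq_along(subset)) {
    i <- subset[k]
    nb <- which(d2all[i, ] < (R[i] + R)^2)
    nb <- setdiff(nb, i)
    p <- sweep(pts * R[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
             (p[, 3] - xyz[j, 3])^2
      acc <- acc & dj2 > R[j]^2
      if (!any(acc)) break
    }
    area[k] <- 4 * pi * R[i]^2 * sum(acc) / n_points
  }
  setNames(area, if (inherits(s, "ca_structure")) s$res_id[subset] else subset)
}

#' Buried surface area between two residue sets
#'
#' BSA = SASA(A alone) + SASA(B alone) - SASA(A and B together), on the
#' residue-sphere model; the remainder of the structure is ignored so the
#' value isolates the A-B interface.
#'
#' @param s a [ca_structure()].
#' @param setA,setB disjoint vectors of author residue numbers.
#' @param probe probe radius (Angstrom, default 1.4).
#' @param radius per-residue sphere radius (Angstrom, default 3.0).
#' @param n_points quadrature points (default 960).
#' @return Buried area in square Angstrom (>= 0 up to quadrature noise).
#' @export
buried_interface_area <- function(s, setA, setB, probe = 1.4, radius = 3.0,
                                  n_points = 960L) {
  stopifnot(inherits(s, "ca_structure"))
  if (length(intersect(setA, setB)))
    stop("precondition error: residue sets overlap")
  ia <- match(setA, s$res_id); ib <- match(setB, s$res_id)
  if (anyNA(ia) || anyNA(ib)) stop("residue set member not in structure")
  sasa_of <- function(idx) {
    sub <- structure_subset(s, idx)
    sum(shrake_rupley_sasa(sub, radius = radius, probe = probe,
                           n_points = n_points))
  }
  sasa_of(ia) + sasa_of(ib) - sasa_of(c(ia, ib))
}
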