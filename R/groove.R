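#' Cylinder approximation of a groove from its observed area and volume
#'
#' A substrate-binding groove measured on a protein surface is reduced to
#' the cylinder of minimum area and volume consistent with the observed
#' groove area A_o (Angstrom^2) and volume V_o (Angstrom^3):
#' \deqn{r = \sqrt{A_o / 4\pi}, \quad h = 4 V_o / A_o, \quad l = A_o / r,}
#' with the closed cylinder area A_c = 2 pi r (r + h) and volume
#' V_c = pi r^2 h, and approximation constants phi = |A_o - A_c| and
#' beta = |V_o - V_c|. Two identities follow analytically: V_c = V_o
#' (hence beta = 0 up to rounding) and l = 4 pi r.
#'
#' @param A_o observed groove area in square Angstrom (> 0).
#' @param V_o observed groove volume in cubic Angstrom (> 0).
#' @return An object of class `cylinder_approx` with fields `A_o`, `V_o`,
#'   `r`, `h`, `l`, `A_c`, `V_c`, `phi`, `beta` (full precision; the print
#'   method rounds to 2 decimals).
#' @export
cylinder_from_groove <- function(A_o, V_o) {
  if (!is.finite(A_o) || !is.finite(V_o) || A_o <= 0 || V_o <= 0)
    stop("precondition error: A_o and V_o must be positive")
  r <- sqrt(A_o / (4 * pi))
  h <- 4 * V_o / A_o
  l <- A_o / r
  A_c <- 2 * pi * r * (r + h)
  V_c <- pi * r^2 * h
  structure(list(A_o = A_o, V_o = V_o, r = r, h = h, l = l,
                 A_c = A_c, V_c = V_c,
                 phi = abs(A_o - A_c), beta = abs(V_o - V_c)),
            class = "cylinder_approx")
}

#' @export
print.cylinder_approx <- function(x, ...) {
  cat(sprintf(
    paste0("<cylinder_approx> A_o %.2f A^2, V_o %.2f A^3\n",
           "  r %.2f  h %.2f  l %.2f  A_c %.2f  V_c %.2f  ",
           "phi %.2f  beta %.2f\n"),
    x$A_o, x$V_o, x$r, x$h, x$l, x$A_c, x$V_c, x$phi, x$beta))
  invisible(x)
}

#' Cylinder approximations for a table of groove measurements
#'
#' @param tab data.frame with columns `A_o` and `V_o` (one groove per row;
#'   other columns are carried through).
#' @return `tab` with appended columns `r`, `h`, `l`, `A_c`, `V_c`, `dA`
#'   (phi) and `dV` (beta), full precision.
#' @export
cylinder_table <- function(tab) {
  stopifnot(all(c("A_o", "V_o") %in% names(tab)))
  fits <- lapply(seq_len(nrow(tab)),
                 function(i) cylinder_from_groove(tab$A_o[i], tab$V_o[i]))
  get <- function(f) vapply(fits, `[[`, numeric(1), f)
  cbind(tab, r = get("r"), h = get("h"), l = get("l"),
        A_c = get("A_c"), V_c = get("V_c"),
        dA = get("phi"), dV = get("beta"))
}

#' Measured groove dimensions of the four characterized class C enzymes
#'
#' Observed wide-groove area/volume pairs (and the published cylinder fit)
#' for the four laboratory-characterized full-length plant class C GH9
#' endoglucanases (UniProt Q5NAT0, Q8LJP6, Q93WY9, Q9ZSP9), as measured on
#' their relaxed homology models.
#'
#' @return data.frame with columns `id`, `organism`, `A_o`, `V_o`, `r`,
#'   `h`, `l`, `A_c`, `V_c`, `dA`, `dV` (published values, 2 decimals).
#' @export
characterized_grooves <- function() {
  read.delim(system.file("extdata", "characterized_grooves.tsv",
                         package = "clefscope"),
             stringsAsFactors = FALSE)
}

#' Published groove cylinder fits of putative class C enzymes
#'
#' Major-groove cylinder dimensions (r, h, l) measured separately over the
#' GH9 and CBM49 domains for 39 putative plant class C enzymes; one entry
#' has no measurable CBM49 groove (NA row).
#'
#' @return data.frame with columns `id`, `organism`, `r_GH9`, `h_GH9`,
#'   `l_GH9`, `r_CBM49`, `h_CBM49`, `l_CBM49`.
#' @export
family_grooves <- function() {
  read.delim(system.file("extdata", "family_grooves.tsv",
                         package = "clefscope"),
             stringsAsFactors = FALSE)
}

#' Grid flood-fill measurement of cavities and grooves
#'
#' Stand-in for interactive surface programs: the structure is modelled as
#' one sphere per residue; a cubic grid over the (padded) bounding box marks
#' cells inside any probe-inflated sphere as obstacles; empty cells
#' reachable from the box boundary are bulk solvent (flood fill,
#' 6-connectivity); the remaining empty cells are pocket/groove candidates.
#' Connected candidate components with volume >= `min_volume` are reported
#' with V_o = cells x spacing^3, A_o = exposed faces x spacing^2 (a voxel
#' surface estimator, which overestimates smooth areas; refine `spacing` to
#' converge), and their lining residues.
#'
#' @param s a [ca_structure()].
#' @param probe probe radius in Angstrom (default 1.4).
#' @param spacing grid spacing in Angstrom, within [0.25, 2.0] (default 0.5).
#' @param min_volume minimum reported component volume (Angstrom^3).
#' @param radius per-residue sphere radius (default 3.0).
#' @return List of `groove_measurement` objects, each with `A_o`, `V_o`,
#'   `lining` (author residue numbers) and `n_cells`; ordered by
#'   decreasing volume.
#' @export
grid_groove_measure <- function(s, probe = 1.4, spacing = 0.5,
                                min_volume = 10, radius = 3.0) {
  stopifnot(inherits(s, "ca_structure"))
  if (length(s$res_id) == 0L) stop("precondition error: empty structure")
  if (spacing < 0.25 || spacing > 2.0)
    stop("spacing must lie in [0.25, 2.0] Angstrom")
  xyz <- s$xyz
  n <- nrow(xyz)
  if (length(radius) == 1L) radius <- rep(radius, n)
  R <- radius + probe
  pad <- max(R) + 2 * spacing
  ## snap the grid origin to a fixed coarse unit so grids at different
  ## spacings share an origin and volume estimates converge cleanly under
  ## spacing refinement
  lo <- floor((apply(xyz, 2, min) - pad) / 2) * 2
  hi <- apply(xyz, 2, max) + pad
  gx <- seq(lo[1], hi[1], by = spacing)
  gy <- seq(lo[2], hi[2], by = spacing)
  gz <- seq(lo[3], hi[3], by = spacing)
  nx <- length(gx); ny <- length(gy); nz <- length(gz)
  obstacle <- array(FALSE, dim = c(nx, ny, nz))
  ## mark cells inside any inflated sphere (loop over residues, local box)
  for (i in seq_len(n)) {
    ix <- which(abs(gx - xyz[i, 1]) <= R[i])
    iy <- which(abs(gy - xyz[i, 2]) <= R[i])
    iz <- which(abs(gz - xyz[i, 3]) <= R[i])
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (gx[ix] - xyz[i, 1])^2
    dy2 <- (gy[iy] - xyz[i, 2])^2
    dz2 <- (gz[iz] - xyz[i, 3])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    obstacle[ix, iy, iz] <- obstacle[ix, iy, iz] | (d2 <= R[i]^2)
  }
  empty <- !obstacle
  ## flood fill of solvent from the boundary by iterated 6-neighbour dilation
  solvent <- array(FALSE, dim = dim(empty))
  solvent[c(1, nx), , ] <- empty[c(1, nx), , ]
  solvent[, c(1, ny), ] <- solvent[, c(1, ny), ] | empty[, c(1, ny), ]
  solvent[, , c(1, nz)] <- solvent[, , c(1, nz)] | empty[, , c(1, nz)]
  repeat {
    grown <- dilate6(solvent) & empty
    if (!any(grown & !solvent)) break
    solvent <- solvent | grown
  }
  pocket <- empty & !solvent
  if (!any(pocket)) return(list())
  comp <- label_components6(pocket)
  ids <- setdiff(unique(as.vector(comp)), 0L)
  sizes <- vapply(ids, function(k) sum(comp == k), integer(1))
  keep <- ids[sizes * spacing^3 >= min_volume]
  if (!length(keep)) return(list())
  keep <- keep[order(sizes[match(keep, ids)], decreasing = TRUE)]
  out <- lapply(keep, function(k) {
    cells <- which(comp == k, arr.ind = TRUE)
    vol <- nrow(cells) * spacing^3
    area <- exposed_faces(comp == k) * spacing^2
    ## lining residues: sphere surface within probe + spacing of the cells
    pts <- cbind(gx[cells[, 1]], gy[cells[, 2]], gz[cells[, 3]])
    lining <- integer(0)
    for (i in seq_len(n)) {
      d <- sqrt(rowSums(sweep(pts, 2, xyz[i, ])^2))
      if (any(abs(d - R[i]) <= probe + spacing) || any(d <= R[i]))
        lining <- c(lining, s$res_id[i])
    }
    structure(list(A_o = area, V_o = vol, lining = lining,
                   n_cells = nrow(cells)),
              class = "groove_measurement")
  })
  out
}

#' @export
print.groove_measurement <- function(x, ...) {
  cat(sprintf(
    "<groove_measurement> V_o %.1f A^3, A_o %.1f A^2, %d lining residues\n",
    x$V_o, x$A_o, length(x$lining)))
  invisible(x)
}

dilate6 <- function(a) {
  d <- dim(a)
  out <- a
  out[-1, , ] <- out[-1, , ] | a[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | a[-1, , ]
  out[, -1, ] <- out[, -1, ] | a[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | a[, -1, ]
  out[, , -1] <- out[, , -1] | a[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | a[, , -1]
  out
}

## 6-connected component labelling by iterated minimum-label propagation.
label_components6 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  lab[mask] <- seq_len(sum(mask))
  repeat {
    nb <- lab
    big <- max(lab) + 1L
    take_min <- function(cur, shifted) {
      shifted[shifted == 0L] <- big
      out <- pmin(cur, shifted)
      out[cur == 0L] <- 0L
      out
    }
    sh <- array(0L, dim = d); sh[-1, , ] <- lab[-d[1], , ]; nb <- take_min(nb, sh)
    sh <- array(0L, dim = d); sh[-d[1], , ] <- lab[-1, , ]; nb <- take_min(nb, sh)
    sh <- array(0L, dim = d); sh[, -1, ] <- lab[, -d[2], ]; nb <- take_min(nb, sh)
    sh <- array(0L, dim = d); sh[, -d[2], ] <- lab[, -1, ]; nb <- take_min(nb, sh)
    sh <- array(0L, dim = d); sh[, , -1] <- lab[, , -d[3]]; nb <- take_min(nb, sh)
    sh <- array(0L, dim = d); sh[, , -d[3]] <- lab[, , -1]; nb <- take_min(nb, sh)
    if (identical(nb, lab)) break
    lab <- nb
  }
  lab
}

exposed_faces <- function(mask) {
  d <- dim(mask)
  cnt <- 0L
  ## faces between a mask cell and a non-mask neighbour (or the array edge)
  cnt <- cnt + sum(mask[1, , ]) + sum(mask[d[1], , ]) +
    sum(mask[-1, , ] & !mask[-d[1], , ]) + sum(mask[-d[1], , ] & !mask[-1, , ])
  cnt <- cnt + sum(mask[, 1, ]) + sum(mask[, d[2], ]) +
    sum(mask[, -1, ] & !mask[, -d[2], ]) + sum(mask[, -d[2], ] & !mask[, -1, ])
  cnt <- cnt + sum(mask[, , 1]) + sum(mask[, , d[3]]) +
    sum(mask[, , -1] & !mask[, , -d[3]]) + sum(mask[, , -d[3]] & !mask[, , -1])
  cnt
}

#' Domain span of a groove
#'
#' @param g a `groove_measurement` (or any list with a `lining` vector of
#'   author residue numbers).
#' @param domains a [domain_annotation()].
#' @return Single label: the set of domains contributing at least one lining
#'   residue, as `"GH9"`, `"L"`, `"CBM49"` for single-domain grooves and a
#'   concatenation in G-L-C order otherwise (`"LC"`, `"GC"`, `"GLC"`).
#' @export
assign_groove_domains <- function(g, domains) {
  lab <- domain_of(domains, g$lining)
  if (anyNA(lab))
    stop("annotation error: unannotated lining residue ",
         g$lining[which(is.na(lab))[1L]])
  present <- unique(lab)
  if (length(present) == 1L) return(present)
  code <- c(GH9 = "G", L = "L", CBM49 = "C")
  paste(code[intersect(c("GH9", "L", "CBM49"), present)], collapse = "")
}
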