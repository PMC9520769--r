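# Conservative finite-volume meshes over the scenario geometries.
#
# All meshes share one graph representation: cells with exact volumes,
# internal faces (i, j, area, half-distances) from which per-solute
# conductances are assembled, and Dirichlet boundary faces where the
# dissolved-oxygen concentration is imposed at the media free surface.
# Every other boundary (vessel walls, base, symmetry axis) is no-flux by
# omission.  Cell volumes sum exactly to the scenario liquid volume.

SOLUTES <- c("o2", "glucose", "lactate")

# Uniform edges covering [0, extent] with target spacing h0.
.uniform_edges <- function(extent, h0) {
  n <- max(2L, ceiling(extent / h0))
  seq(0, extent, length.out = n + 1L)
}

# Graded edges from `from` to `to`, growing from h0 by `grow` per cell up
# to hmax, then scaled so the last edge lands exactly on `to`.
.graded_edges <- function(from, to, h0, grow = 1.35, hmax = Inf) {
  span <- to - from
  if (span <= 1e-15) return(numeric(0))
  sizes <- c()
  h <- h0
  while (sum(sizes) < span) {
    h <- min(h * grow, hmax)
    sizes <- c(sizes, h)
  }
  sizes <- sizes * span / sum(sizes)
  from + cumsum(sizes)
}

.centers <- function(edges) (edges[-1] + edges[-length(edges)]) / 2
.widths  <- function(edges) diff(edges)

# D matrix (n x 3, m^2/h) from region labels.
.diff_matrix <- function(region, scenario) {
  D <- matrix(0, length(region), 3, dimnames = list(NULL, SOLUTES))
  for (s in SOLUTES) {
    D[, s] <- ifelse(region == 2L,
                     scenario$construct$diffusivities[[s]],
                     scenario$media_diffusivities[[s]]) * 3600
  }
  D
}

.new_mesh <- function(symmetry, scenario, vol, count, region, rho, coords,
                      faces, dirichlet_o2, geom, mono = NULL) {
  structure(list(
    symmetry = symmetry, n = length(vol), vol = vol, count = count,
    region = region, rho = rho, coords = coords, faces = faces,
    dirichlet_o2 = dirichlet_o2, D = .diff_matrix(region, scenario),
    geom = geom, mono = mono,
    bc_o2 = dissolved_oxygen(scenario$environment),
    glucose_fresh = scenario$glucose_mM), class = "rd_mesh")
}

#' @export
print.rd_mesh <- function(x, ...) {
  cat(sprintf(
    "<rd_mesh> %s, %d cells (%d construct), total volume %.4g ml\n",
    x$symmetry, x$n, sum(x$region == 2L), sum(x$vol * x$count) * 1e6))
  invisible(x)
}

# ---- planar 1D column (monolayer vessels) -------------------------------

.mesh_planar <- function(scenario, resolution) {
  vessel <- scenario$vessel
  area <- .VESSEL_CATALOGUE[[vessel$kind]]$base_area_cm2 * 1e-4 # m^2
  H <- vessel_fill_height(vessel, vessel$media_volume_ml * 1e-6)
  edges <- .uniform_edges(H, H / max(resolution, 8L))
  nz <- length(edges) - 1L
  dz <- .widths(edges)
  zc <- .centers(edges)
  vol <- area * dz
  faces <- data.frame(i = seq_len(nz - 1L), j = seq_len(nz - 1L) + 1L,
                      area = area, di = dz[-nz] / 2, dj = dz[-1] / 2,
                      wi = 1, wj = 1)
  dir_o2 <- data.frame(cell = nz, area = area, dist = dz[nz] / 2)
  mono <- list(cell = 1L, area_cm2 = area * 1e4,
               pop = scenario$construct$seeding)
  .new_mesh("planar1D", scenario, vol, rep(1, nz), rep(1L, nz), rep(0, nz),
            data.frame(z = zc), faces, dir_o2,
            geom = list(nz = nz, z = zc, dz = dz, area = area, H = H),
            mono = mono)
}

# ---- axisymmetric r-z mesh (bead, cylinder, pellet in a vessel) ---------

.mesh_axisym <- function(scenario, resolution, grow = 1.35) {
  cs <- scenario$construct
  vessel <- scenario$vessel
  v_total <- vessel$media_volume_ml * 1e-6 + cs$volume_m3
  H <- vessel_fill_height(vessel, v_total)
  cone <- vessel_shape(vessel) == "truncated_cone"
  rwall <- if (cone) function(z) cone_radius_at(vessel, z)
           else { Rw <- vessel_radius(vessel); function(z) rep(Rw, length(z)) }
  if (cs$kind %in% c("bead", "pellet")) {
    Rc <- cs$radius_m
    extent_r <- Rc; extent_z <- 2 * Rc
    min_dim <- 2 * Rc
    in_construct <- function(r, z) r^2 + (z - Rc)^2 <= Rc^2
  } else {
    extent_r <- cs$radius_m; extent_z <- cs$height_m
    min_dim <- min(cs$height_m, 2 * cs$radius_m)
    in_construct <- function(r, z) r <= cs$radius_m & z <= cs$height_m
  }
  h0 <- min_dim / resolution
  r_max <- rwall(H)
  r_edges <- c(.uniform_edges(extent_r, h0),
               .graded_edges(extent_r, r_max, h0, grow, hmax = r_max / 6))
  z_edges <- c(.uniform_edges(extent_z, h0),
               .graded_edges(extent_z, H, h0, grow, hmax = H / 6))
  nr <- length(r_edges) - 1L; nz <- length(z_edges) - 1L
  rc <- .centers(r_edges); zc <- .centers(z_edges)
  dr <- .widths(r_edges); dz <- .widths(z_edges)
  ring_area <- pi * (r_edges[-1]^2 - r_edges[-(nr + 1L)]^2) # per radial cell

  # number of radial cells kept in each z layer (cone trimming) and the
  # exact layer volume the kept cells must sum to
  keep <- integer(nz); layer_vol <- numeric(nz)
  for (jz in seq_len(nz)) {
    rw_c <- rwall(zc[jz])
    k <- max(1L, sum(r_edges[-(nr + 1L)] < rw_c - 1e-15))
    if (cone) {
      a <- rwall(z_edges[jz]); b <- rwall(z_edges[jz + 1L])
      layer_vol[jz] <- pi * dz[jz] * (a^2 + a * b + b^2) / 3
      # partial outer cell must keep positive volume
      while (k > 1L && layer_vol[jz] - sum(ring_area[seq_len(k - 1L)]) * dz[jz] <=
             0.05 * ring_area[k - 1L] * dz[jz])
        k <- k - 1L
    } else {
      layer_vol[jz] <- pi * rw_c^2 * dz[jz]
    }
    keep[jz] <- k
  }

  idx <- matrix(NA_integer_, nr, nz)
  cid <- 0L
  vol <- numeric(0); cr <- numeric(0); cz <- numeric(0)
  for (jz in seq_len(nz)) {
    k <- keep[jz]
    v <- ring_area[seq_len(k)] * dz[jz]
    v[k] <- layer_vol[jz] - sum(v[-k]) # exact layer closure
    idx[seq_len(k), jz] <- cid + seq_len(k)
    cid <- cid + k
    vol <- c(vol, v); cr <- c(cr, rc[seq_len(k)]); cz <- c(cz, rep(zc[jz], k))
  }
  n <- cid
  region <- ifelse(in_construct(cr, cz), 2L, 1L)
  # rescale density so the meshed construct holds the nominal cell number
  v_meshed <- sum(vol[region == 2L])
  if (cs$density > 0 && v_meshed <= 0)
    stop("mesh too coarse: construct region resolved by no cells")
  rho <- ifelse(region == 2L,
                if (v_meshed > 0) cs$density * cs$volume_m3 / v_meshed else 0,
                0)

  # radial faces
  fi <- c(); fj <- c(); fa <- c(); fdi <- c(); fdj <- c()
  for (jz in seq_len(nz)) {
    k <- keep[jz]
    if (k > 1L) {
      ii <- idx[seq_len(k - 1L), jz]; jj <- idx[seq_len(k - 1L) + 1L, jz]
      fi <- c(fi, ii); fj <- c(fj, jj)
      fa <- c(fa, 2 * pi * r_edges[seq_len(k - 1L) + 1L] * dz[jz])
      fdi <- c(fdi, dr[seq_len(k - 1L)] / 2)
      fdj <- c(fdj, dr[seq_len(k - 1L) + 1L] / 2)
    }
  }
  # vertical faces (capped by the wall radius at the interface)
  for (jz in seq_len(nz - 1L)) {
    k <- min(keep[jz], keep[jz + 1L])
    rw_f <- rwall(z_edges[jz + 1L])
    for (ir in seq_len(k)) {
      a <- pi * (min(r_edges[ir + 1L], rw_f)^2 - r_edges[ir]^2)
      if (a <= 0) next
      fi <- c(fi, idx[ir, jz]); fj <- c(fj, idx[ir, jz + 1L])
      fa <- c(fa, a); fdi <- c(fdi, dz[jz] / 2); fdj <- c(fdj, dz[jz + 1L] / 2)
    }
  }
  faces <- data.frame(i = fi, j = fj, area = fa, di = fdi, dj = fdj,
                      wi = 1, wj = 1)
  k_top <- keep[nz]
  top_cells <- idx[seq_len(k_top), nz]
  top_area <- ring_area[seq_len(k_top)]
  top_area[k_top] <- vol[top_cells[k_top]] / dz[nz]
  dir_o2 <- data.frame(cell = top_cells, area = top_area, dist = dz[nz] / 2)
  .new_mesh("axisymmetric2D", scenario, vol, rep(1, n), region, rho,
            data.frame(r = cr, z = cz), faces, dir_o2,
            geom = list(nr = nr, nz = nz, idx = idx, r = rc, z = zc,
                        dr = dr, dz = dz, H = H,
                        construct_extent_z = extent_z))
}

# ---- reduced-order multi-bead compartment mesh --------------------------

# N identical spherical beads, each resolved as a 1D shell mesh, coupled to
# a 1D vertical media column through a film/spreading resistance
# (access conductance 4*pi*D_media*R in series with the outer half-shell).
.mesh_multibead <- function(scenario, resolution) {
  cs <- scenario$construct
  if (cs$kind != "bead") stop("compartment model requires bead constructs")
  N <- scenario$n_constructs
  vessel <- scenario$vessel
  area <- .VESSEL_CATALOGUE[[vessel$kind]]$base_area_cm2 * 1e-4
  v_media <- vessel$media_volume_ml * 1e-6
  H <- (v_media + N * cs$volume_m3) / area
  Rb <- cs$radius_m
  nb <- max(10L, ceiling(resolution / 2))
  r_edges <- seq(0, Rb, length.out = nb + 1L)
  shell_vol <- 4 / 3 * pi * diff(r_edges^3)
  rb_c <- .centers(r_edges)
  z_edges <- .uniform_edges(H, H / max(resolution, 10L))
  nzm <- length(z_edges) - 1L
  dz <- .widths(z_edges); zc <- .centers(z_edges)
  media_vol <- v_media * dz / H # media volume distributed over the column
  n <- nb + nzm
  ib <- seq_len(nb); im <- nb + seq_len(nzm)
  vol <- c(shell_vol, media_vol)
  count <- c(rep(N, nb), rep(1, nzm))
  region <- c(rep(2L, nb), rep(1L, nzm))
  rho <- c(rep(cs$density, nb), rep(0, nzm))
  coords <- data.frame(r = c(rb_c, rep(0, nzm)), z = c(rep(Rb, nb), zc))
  # internal shell faces
  faces <- data.frame(
    i = ib[-nb], j = ib[-nb] + 1L,
    area = 4 * pi * r_edges[2:nb]^2,
    di = diff(r_edges)[-nb] / 2, dj = diff(r_edges)[-1] / 2,
    wi = 1, wj = 1)
  # media column faces
  if (nzm > 1L)
    faces <- rbind(faces, data.frame(
      i = im[-nzm], j = im[-nzm] + 1L, area = area,
      di = dz[-nzm] / 2, dj = dz[-1] / 2, wi = 1, wj = 1))
  # bead <-> media coupling at the layer containing the bead centre:
  # half-shell resistance in series with the spherical access resistance
  # 1/(4 pi D R); encoded as an equivalent (area, di, dj) face.
  j_couple <- im[max(1L, findInterval(Rb, z_edges))]
  faces <- rbind(faces, data.frame(
    i = nb, j = j_couple, area = 4 * pi * Rb^2,
    di = Rb - rb_c[nb], dj = Rb, wi = 1, wj = N))
  dir_o2 <- data.frame(cell = im[nzm], area = area, dist = dz[nzm] / 2)
  .new_mesh("compartment", scenario, vol, count, region, rho, coords,
            faces, dir_o2,
            geom = list(nb = nb, nzm = nzm, r = rb_c, z = zc, H = H,
                        n_beads = N))
}

#' Build the finite-volume mesh for a scenario
#'
#' Monolayer vessels reduce to a 1D vertical media column (lateral
#' uniformity); a single bead, cylinder or pellet in a vessel is meshed as
#' an axisymmetric r-z domain with the construct resolved at `resolution`
#' cells across its smallest dimension and a geometrically graded media
#' region; multi-bead scenarios use the reduced-order compartment mesh
#' (spherically symmetric representative bead coupled to a 1D media
#' column).  Dissolved oxygen is fixed at the media free surface; all other
#' boundaries, including the vessel base in contact with culture plastic,
#' are no-flux.
#'
#' @param scenario A [culture_scenario()].
#' @param resolution Cells across the smallest construct dimension
#'   (default 40).
#' @return An object of class `rd_mesh`.
#' @export
build_mesh <- function(scenario, resolution = 40) {
  validate_scenario(scenario)
  if (resolution < 4) stop("resolution must be at least 4")
  cs <- scenario$construct
  if (cs$kind == "monolayer") .mesh_planar(scenario, resolution)
  else if (scenario$n_constructs > 1L) .mesh_multibead(scenario, resolution)
  else .mesh_axisym(scenario, resolution)
}

# Per-solute sparse diffusion operators: dC/dt = A %*% C + b (+ sources).
assemble_ops <- function(mesh) {
  n <- mesh$n
  f <- mesh$faces
  ops <- list()
  for (s in SOLUTES) {
    Ds <- mesh$D[, s]
    if (nrow(f)) {
      g <- f$area / (f$di / Ds[f$i] + f$dj / Ds[f$j])
      ii <- c(f$i, f$i, f$j, f$j)
      jj <- c(f$i, f$j, f$j, f$i)
      xx <- c(-f$wi * g / mesh$vol[f$i], f$wi * g / mesh$vol[f$i],
              -f$wj * g / mesh$vol[f$j], f$wj * g / mesh$vol[f$j])
    } else {
      ii <- jj <- integer(0); xx <- numeric(0)
    }
    b <- numeric(n)
    dir <- NULL
    if (s == "o2" && nrow(mesh$dirichlet_o2)) {
      d <- mesh$dirichlet_o2
      gd <- d$area * Ds[d$cell] / d$dist
      ii <- c(ii, d$cell); jj <- c(jj, d$cell)
      xx <- c(xx, -gd / mesh$vol[d$cell])
      b[d$cell] <- b[d$cell] + gd * mesh$bc_o2 / mesh$vol[d$cell]
      dir <- list(cells = d$cell, g = gd, value = mesh$bc_o2)
    }
    A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                              repr = "C")
    ops[[s]] <- list(A = A, b = b, dirichlet = dir)
  }
  ops
}
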