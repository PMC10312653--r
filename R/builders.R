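# Structure and topology builders: single chains from a protein spec,
# multi-chain slab boxes packed to a coil budget.

#' Construct a molecular system
#' @param coords n x 3 coordinate matrix (nm)
#' @param box orthorhombic box lengths (nm)
#' @param beads per-bead metadata data.frame
#' @param bonds,angles,torsions bonded term tables
#' @param spec originating [protein_spec()] (single-chain template)
#' @keywords internal
#' @noRd
new_cc_system <- function(coords, box, beads, bonds, angles, torsions,
                          spec = NULL) {
  stopifnot(is.matrix(coords), ncol(coords) == 3, all(is.finite(coords)),
            length(box) == 3, all(box > 0), nrow(beads) == nrow(coords))
  structure(list(coords = coords, box = as.numeric(box), beads = beads,
                 bonds = bonds, angles = angles, torsions = torsions,
                 spec = spec),
            class = "cc_system")
}

#' @export
print.cc_system <- function(x, ...) {
  cat(sprintf("cc_system: %d beads, %d chain(s), box %g x %g x %g nm\n",
              nrow(x$coords), length(unique(x$beads$chain)),
              x$box[1], x$box[2], x$box[3]))
  cat(sprintf("  %d bonds, %d angles, %d torsions; %d sticky beads\n",
              nrow(x$bonds), nrow(x$angles), nrow(x$torsions),
              sum(x$beads$sticky)))
  invisible(x)
}

#' Number of beads in a system
#' @param system a `cc_system`
#' @export
n_beads <- function(system) nrow(system$coords)

#' Build a single-chain system from a protein spec
#'
#' One bead per residue. The whole chain — coils and linkers alike — is
#' initialized as an ideal alpha-helical C-alpha trace; during NVT
#' equilibration the weakly-restrained linkers relax out of the helix
#' while coils stay helical. Bonded terms take coil parameters when all
#' participating beads belong to the same coil segment, linker parameters
#' otherwise (so terms spanning a coil/linker junction are soft).
#'
#' @param spec a [protein_spec()]
#' @param ff a [default_forcefield()]
#' @param box box lengths in nm; `NULL` chooses a cube comfortably larger
#'   than the initial helix
#' @return a `cc_system` with one chain
#' @examples
#' spec <- make_coil_protein(2, "dimer")   # 2-coil-1-linker, 32/25/32
#' sys <- build_protein(spec, default_forcefield("dimer"))
#' n_beads(sys)        # 89
#' nrow(sys$bonds)     # 88
#' @export
build_protein <- function(spec, ff = default_forcefield(), box = NULL) {
  stopifnot(inherits(spec, "protein_spec"), inherits(ff, "cc_forcefield"))
  lens <- vapply(spec$segments, `[[`, integer(1), "length")
  n <- sum(lens)
  seg_of <- rep(seq_along(spec$segments), lens)
  kind_of <- vapply(spec$segments, `[[`, character(1), "kind")[seg_of]
  # residue index within its segment, 0-based
  res_in_seg <- unlist(lapply(lens, function(l) seq_len(l) - 1L))

  coil_counter <- 0L
  coil_id <- integer(n)
  itype <- rep("inert", n)
  class_of <- ifelse(kind_of == "linker", "linker_inert", "backbone")
  sticky <- logical(n)
  for (s in seq_along(spec$segments)) {
    seg <- spec$segments[[s]]
    if (seg$kind != "coil") next
    coil_counter <- coil_counter + 1L
    sel <- which(seg_of == s)
    coil_id[sel] <- coil_counter
    hp <- res_in_seg[sel] %% 7L
    core_frac <- if (is.null(seg$sticky_core_fraction)) 1
                 else seg$sticky_core_fraction
    margin <- seg$length * (1 - core_frac) / 2
    in_core <- res_in_seg[sel] >= margin &
      res_in_seg[sel] < seg$length - margin
    is_sticky <- hp %in% seg$sticky_pattern & in_core
    sticky[sel] <- is_sticky
    # sticky columns are sub-typed by the parity of their 7-residue
    # period: a partner docking in-register pairs like with like, while
    # a half-period register shift faces mismatched sub-types and gains
    # no attraction. This pins docking to the in-register pose and
    # suppresses axially staggered chaining (which would otherwise give
    # dimer-forming coils an effective valence above one).
    parity <- (res_in_seg[sel] %/% 7L) %% 2L
    itype[sel][is_sticky] <- paste0(seg$coil_type_id, ":",
                                    parity[is_sticky])
    primary_face <- hp %in% .heptad_faces[[1]]
    class_of[sel] <- ifelse(is_sticky & primary_face, "coil_sticky",
                            ifelse(is_sticky, "multimer_driver", "backbone"))
  }

  coords <- ideal_helix_coords(n, ff$helix)
  if (is.null(box)) {
    side <- max(6, n * ff$helix$rise + 4)
    box <- rep(side, 3)
  }
  # center the chain in the box
  coords <- sweep(coords, 2, colMeans(coords))
  coords <- sweep(coords, 2, box / 2, `+`)

  beads <- data.frame(
    chain = 1L, segment = seg_of, kind = kind_of, coil_id = coil_id,
    class = class_of, itype = itype, sticky = sticky, mass = ff$mass,
    stringsAsFactors = FALSE
  )

  term_params <- function(idx_list) {
    # coil parameters iff every bead of the term is in one coil segment
    vapply(idx_list, function(ix) {
      segs <- unique(seg_of[ix])
      length(segs) == 1L && kind_of[ix[1]] == "coil"
    }, logical(1))
  }
  bp <- ff$bonded
  mk_bonds <- function() {
    if (n < 2) return(data.frame(ai = integer(), aj = integer(),
                                 r0 = numeric(), kf = numeric()))
    ai <- seq_len(n - 1L); aj <- ai + 1L
    is_coil <- term_params(Map(c, ai, aj))
    data.frame(ai = ai, aj = aj,
               r0 = ifelse(is_coil, bp$coil$bond[["r0"]], bp$linker$bond[["r0"]]),
               kf = ifelse(is_coil, bp$coil$bond[["k"]], bp$linker$bond[["k"]]))
  }
  mk_angles <- function() {
    if (n < 3) return(data.frame(ai = integer(), aj = integer(),
                                 ak = integer(), theta0 = numeric(),
                                 kf = numeric()))
    ai <- seq_len(n - 2L); aj <- ai + 1L; ak <- ai + 2L
    is_coil <- term_params(Map(c, ai, aj, ak))
    data.frame(ai = ai, aj = aj, ak = ak,
               theta0 = ifelse(is_coil, bp$coil$angle[["theta0"]],
                               bp$linker$angle[["theta0"]]),
               kf = ifelse(is_coil, bp$coil$angle[["k"]], bp$linker$angle[["k"]]))
  }
  mk_torsions <- function() {
    if (n < 4) return(data.frame(ai = integer(), aj = integer(),
                                 ak = integer(), al = integer(),
                                 phi0 = numeric(), kf = numeric(),
                                 mult = integer()))
    ai <- seq_len(n - 3L); aj <- ai + 1L; ak <- ai + 2L; al <- ai + 3L
    is_coil <- term_params(Map(c, ai, aj, ak, al))
    data.frame(ai = ai, aj = aj, ak = ak, al = al,
               phi0 = ifelse(is_coil, bp$coil$torsion[["phi0"]],
                             bp$linker$torsion[["phi0"]]),
               kf = ifelse(is_coil, bp$coil$torsion[["k"]],
                           bp$linker$torsion[["k"]]),
               mult = as.integer(bp$coil$torsion[["mult"]]))
  }

  new_cc_system(coords, box, beads, mk_bonds(), mk_angles(), mk_torsions(),
                spec = spec)
}

# replicate a single-chain template's metadata and bonded tables
.replicate_topology <- function(single, copies) {
  n <- n_beads(single)
  n_coil <- max(single$beads$coil_id)
  beads <- single$beads[rep(seq_len(n), copies), , drop = FALSE]
  off <- rep((seq_len(copies) - 1L), each = n)
  beads$chain <- off + 1L
  beads$coil_id <- ifelse(beads$coil_id > 0L,
                          beads$coil_id + rep((seq_len(copies) - 1L) * n_coil,
                                              each = n), 0L)
  rownames(beads) <- NULL
  shift_tab <- function(tab, cols) {
    out <- tab[rep(seq_len(nrow(tab)), copies), , drop = FALSE]
    o <- rep((seq_len(copies) - 1L) * n, each = nrow(tab))
    for (cl in cols) out[[cl]] <- out[[cl]] + o
    rownames(out) <- NULL
    out
  }
  list(beads = beads,
       bonds = shift_tab(single$bonds, c("ai", "aj")),
       angles = shift_tab(single$angles, c("ai", "aj", "ak")),
       torsions = shift_tab(single$torsions, c("ai", "aj", "ak", "al")))
}

#' Plan how many protein copies fit a coil budget
#'
#' @param spec a [protein_spec()]
#' @param coil_budget total coil segments allowed in the box
#' @return list with `copies` (the maximal copy count whose total coil
#'   count does not exceed the budget) and `coils_placed`
#' @examples
#' plan_packing(make_coil_protein(4), 450)  # 112 copies, 448 coils
#' @export
plan_packing <- function(spec, coil_budget = 450L) {
  nc <- n_coils(spec)
  copies <- coil_budget %/% nc
  list(copies = as.integer(copies), coils_placed = as.integer(copies * nc),
       n_coils_per_copy = nc)
}

#' Pack protein copies into a slab starting box
#'
#' Random rigid placement (uniform random rotation + translation) of
#' protein conformations into an orthorhombic periodic box, rejecting any
#' placement that brings a bead within `tolerance` of an already placed
#' chain (minimum-image distances). The copy count is the maximum number
#' whose coils fit `coil_budget`; copies are assigned round-robin over
#' the conformation pool. Placement is reproducible under `seed`.
#'
#' @param single a single-chain `cc_system` template (topology source)
#' @param config_pool list of n x 3 coordinate matrices (equilibrated
#'   single-molecule conformations); `NULL` uses the template coordinates
#' @param coil_budget total coil segments per box (default 450)
#' @param copies override the copy count directly (ignores `coil_budget`)
#' @param box box lengths in nm (default `c(25, 25, 100)`)
#' @param tolerance minimum inter-chain bead distance in nm (default 1.0)
#' @param seed RNG seed for placement
#' @param max_attempts placement attempts per copy before giving up
#' @return multi-chain `cc_system`
#' @export
pack_slab_box <- function(single, config_pool = NULL, coil_budget = 450L,
                          copies = NULL, box = c(25, 25, 100),
                          tolerance = 1.0, seed = 1L, max_attempts = 5000L) {
  stopifnot(inherits(single, "cc_system"), tolerance > 0, length(box) == 3)
  if (is.null(config_pool)) config_pool <- list(single$coords)
  stopifnot(length(config_pool) >= 1)
  for (cf in config_pool)
    stopifnot(is.matrix(cf), nrow(cf) == n_beads(single), ncol(cf) == 3)
  if (is.null(copies)) {
    pl <- plan_packing(single$spec, coil_budget)
    copies <- pl$copies
  }
  copies <- as.integer(copies)
  stopifnot(copies >= 1)
  assignment <- ((seq_len(copies) - 1L) %% length(config_pool)) + 1L
  pool_centered <- lapply(config_pool, function(m) sweep(m, 2, colMeans(m)))
  res <- cpp_pack_box(pool_centered, assignment, as.numeric(box),
                      tolerance, as.integer(seed), as.integer(max_attempts))
  if (!res$ok) {
    stop(sprintf(
      "packing failed at copy %d of %d (achieved packing fraction %.3f of requested copies); enlarge the box or lower the tolerance",
      res$placed + 1L, copies, res$placed / copies), call. = FALSE)
  }
  topo <- .replicate_topology(single, copies)
  new_cc_system(res$coords, box, topo$beads, topo$bonds, topo$angles,
                topo$torsions, spec = single$spec)
}
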