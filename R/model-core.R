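# Domain types and force-field parameterization: bead classes, multimer
# modes, coil/linker segment specs, protein architectures, the default
# force field and the maximally specific interaction scheme.

#' Bead classes of the coarse-grained framework
#'
#' Four classes of one-bead-per-residue C-alpha beads: plain `backbone`
#' beads of coil segments, `coil_sticky` beads carrying the primary
#' coil-coil attraction, `multimer_driver` beads (additional sticky faces
#' that raise the multimerization valence beyond a dimer) and
#' `linker_inert` beads, which interact with everything through excluded
#' volume only — linkers are equally happy in solvent and protein, so they
#' carry no attraction.
#'
#' @param mass bead mass in amu (default 109, the average amino-acid mass)
#' @param sigma Lennard-Jones diameter in nm (default 0.47)
#' @param base_epsilon excluded-volume interaction strength in kJ/mol used
#'   for all repulsive-only pairs (default 0.1)
#' @return a data.frame with one row per bead class
#' @export
bead_classes <- function(mass = 109, sigma = 0.47, base_epsilon = 0.1) {
  stopifnot(mass > 0, sigma > 0, base_epsilon >= 0)
  data.frame(
    name = c("backbone", "coil_sticky", "multimer_driver", "linker_inert"),
    mass = mass,
    sigma = sigma,
    base_epsilon = base_epsilon,
    attractive = c(FALSE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

# Sticky "faces" around the helix axis, as heptad positions (0-based
# within the 7-residue repeat, position 0 = heptad a). With the ideal
# 100 deg/residue twist a heptad position repeats every ~2 turns with a
# -20 degree offset, i.e. a near-axial column of beads. One face is a
# pair of columns only 40 degrees apart — {0,4} at 0/40 degrees,
# {1,5} at 100/140, {2,6} at 200/240 — compact enough that a single
# partner helix covers the whole face while a second one cannot dock on
# the free column without steric overlap with the first (two helix axes
# 40 degrees apart around the host would sit ~0.65 nm apart, far below
# bead contact distance). A coil presents (max_valence - 1) faces, so
# excluded volume caps the number of simultaneous partners. A classic
# a/d face ({0,3}, 60 degrees apart) turns out to be wide enough to
# host two partners and gives every coil an effective valence of two,
# defeating the dimer mode — hence the compact 40-degree faces.
.heptad_faces <- list(c(0L, 4L), c(1L, 5L), c(2L, 6L))

#' Multimerization mode of a coil segment
#'
#' A coil segment can be parameterized to favour dimers, trimers or
#' tetramers. The mode fixes the coil-coil sticky interaction strength
#' (`epsilon_coil`) and the maximum valence. Defaults: 5.5 kJ/mol for
#' dimer-forming coils and 4.0 kJ/mol for trimer- and tetramer-forming
#' coils, the values at which the parameterization balances multimer
#' formation against runaway aggregation.
#'
#' @param name one of `"dimer"`, `"trimer"`, `"tetramer"`
#' @param epsilon_coil sticky interaction strength in kJ/mol; `NULL` uses
#'   the mode default
#' @return an object of class `multimer_mode`
#' @examples
#' multimer_mode("dimer")$epsilon_coil    # 5.5
#' multimer_mode("tetramer")$epsilon_coil # 4.0
#' @export
multimer_mode <- function(name = c("dimer", "trimer", "tetramer"),
                          epsilon_coil = NULL) {
  if (!is.character(name) || length(name) != 1 ||
      !name %in% c("dimer", "trimer", "tetramer")) {
    stop("unknown multimer mode '", paste(name, collapse = ","),
         "'; valid modes are: dimer, trimer, tetramer", call. = FALSE)
  }
  defaults <- c(dimer = 5.5, trimer = 4.0, tetramer = 4.0)
  valence <- c(dimer = 2L, trimer = 3L, tetramer = 4L)
  if (is.null(epsilon_coil)) epsilon_coil <- unname(defaults[name])
  stopifnot(is.numeric(epsilon_coil), length(epsilon_coil) == 1,
            epsilon_coil > 0)
  n_faces <- valence[[name]] - 1L
  structure(list(
    name = name,
    epsilon_coil = epsilon_coil,
    max_valence = valence[[name]],
    n_faces = n_faces,
    sticky_pattern = sort(unlist(.heptad_faces[seq_len(n_faces)]))
  ), class = "multimer_mode")
}

#' @export
print.multimer_mode <- function(x, ...) {
  cat(sprintf("multimer mode '%s': epsilon_coil = %g kJ/mol, max valence %d, %d sticky face(s) at heptad positions {%s}\n",
              x$name, x$epsilon_coil, x$max_valence, x$n_faces,
              paste(x$sticky_pattern, collapse = ",")))
  invisible(x)
}

#' Coil segment specification
#'
#' A helical sticker of at least one heptad. `coil_type_id` labels the
#' coil's interaction specificity: under the maximally specific scheme,
#' sticky beads attract only sticky beads of the *same* type on *other*
#' chains.
#'
#' @param length number of residues (>= 7)
#' @param coil_type_id character label for interaction specificity
#' @param mode a [multimer_mode()] (or mode name)
#' @param sticky_pattern heptad positions (0..6) carrying sticky beads;
#'   `NULL` uses the mode's face pattern
#' @param sticky_core_fraction central fraction of the segment that
#'   carries the sticky beads (default 1: the full coil). Values below 1
#'   confine the columns to the coil's core so a partner must dock
#'   centre-on-centre; this suppresses axially staggered chaining of
#'   dimer-mode coils at the price of much weaker multimer formation in
#'   the trimer and tetramer modes, so the default keeps the full
#'   column and accepts the imperfect specificity.
#' @export
coil_segment <- function(length = 32L, coil_type_id, mode = "dimer",
                         sticky_pattern = NULL,
                         sticky_core_fraction = 1) {
  if (is.character(mode)) mode <- multimer_mode(mode)
  stopifnot(inherits(mode, "multimer_mode"))
  length <- as.integer(length)
  if (is.na(length) || length < 7L)
    stop("coil segment length must be >= 7 residues (one heptad)", call. = FALSE)
  if (missing(coil_type_id) || is.null(coil_type_id) ||
      !nzchar(as.character(coil_type_id)[1]))
    stop("coil segment requires a coil_type_id", call. = FALSE)
  if (is.null(sticky_pattern)) sticky_pattern <- mode$sticky_pattern
  sticky_pattern <- as.integer(sticky_pattern)
  if (any(sticky_pattern < 0L | sticky_pattern > 6L))
    stop("sticky_pattern positions must lie in 0..6", call. = FALSE)
  stopifnot(sticky_core_fraction > 0, sticky_core_fraction <= 1)
  structure(list(kind = "coil", length = length,
                 coil_type_id = as.character(coil_type_id)[1],
                 mode = mode, sticky_pattern = sticky_pattern,
                 sticky_core_fraction = sticky_core_fraction),
            class = c("coil_segment", "cc_segment"))
}

#' Linker segment specification
#'
#' A disordered, inert spacer: its beads have excluded volume but no
#' attraction toward any other bead.
#'
#' @param length number of residues (>= 1)
#' @export
linker_segment <- function(length = 25L) {
  length <- as.integer(length)
  if (is.na(length) || length < 1L)
    stop("linker segment length must be >= 1", call. = FALSE)
  structure(list(kind = "linker", length = length),
            class = c("linker_segment", "cc_segment"))
}

#' Protein architecture: an ordered list of coil and linker segments
#'
#' @param name protein name
#' @param segments list of [coil_segment()] / [linker_segment()] objects
#' @return an object of class `protein_spec`
#' @seealso [make_coil_protein()] for the standard n-coil-(n-1)-linker
#'   architectures
#' @export
protein_spec <- function(name, segments) {
  stopifnot(is.character(name), length(name) == 1, is.list(segments))
  if (!all(vapply(segments, inherits, logical(1), "cc_segment")))
    stop("segments must be coil_segment / linker_segment objects", call. = FALSE)
  kinds <- vapply(segments, `[[`, character(1), "kind")
  if (!any(kinds == "coil"))
    stop("a protein spec needs at least one coil segment", call. = FALSE)
  if (any(vapply(segments, `[[`, integer(1), "length") < 1L))
    stop("zero-length segment", call. = FALSE)
  structure(list(name = name, segments = segments), class = "protein_spec")
}

#' @export
print.protein_spec <- function(x, ...) {
  cat(sprintf("protein '%s': %d coil(s), %d linker(s), %d residues\n",
              x$name, n_coils(x), n_linkers(x), n_residues(x)))
  invisible(x)
}

#' Count coil segments of a protein spec
#' @param spec a [protein_spec()]
#' @export
n_coils <- function(spec) {
  sum(vapply(spec$segments, `[[`, character(1), "kind") == "coil")
}

#' Count linker segments of a protein spec
#' @param spec a [protein_spec()]
#' @export
n_linkers <- function(spec) {
  sum(vapply(spec$segments, `[[`, character(1), "kind") == "linker")
}

#' Total residue (bead) count of a protein spec
#' @param spec a [protein_spec()]
#' @export
n_residues <- function(spec) {
  sum(vapply(spec$segments, `[[`, integer(1), "length"))
}

#' Build a standard alternating n-coil-(n-1)-linker protein
#'
#' The named architectures of the framework ("2-coil-1-linker",
#' "3-coil-2-linker", ...) alternate coil and linker segments, starting
#' and ending with a coil. Under the maximally specific scheme every coil
#' position gets its own `coil_type_id` ("C1", "C2", ...), so a coil can
#' only bind the equivalent coil of another chain.
#'
#' @param n_coils number of coil segments (>= 1)
#' @param mode a [multimer_mode()] or mode name applied to every coil
#' @param coil_length residues per coil segment (default 32)
#' @param linker_length residues per linker segment (default 25)
#' @param name protein name; default e.g. `"3-coil-2-linker-dimer"`
#' @export
make_coil_protein <- function(n_coils, mode = "dimer", coil_length = 32L,
                              linker_length = 25L, name = NULL) {
  if (is.character(mode)) mode <- multimer_mode(mode)
  n_coils <- as.integer(n_coils)
  stopifnot(n_coils >= 1L)
  segs <- list()
  for (i in seq_len(n_coils)) {
    segs[[length(segs) + 1L]] <-
      coil_segment(coil_length, coil_type_id = paste0("C", i), mode = mode)
    if (i < n_coils)
      segs[[length(segs) + 1L]] <- linker_segment(linker_length)
  }
  if (is.null(name))
    name <- sprintf("%d-coil-%d-linker-%s", n_coils, n_coils - 1L, mode$name)
  protein_spec(name, segs)
}

# ---------------------------------------------------------------------------
# Bonded parameters

#' Bonded parameters for coil and linker segments
#'
#' Harmonic pseudo-bonds and pseudo-angles plus a periodic (multiplicity 1)
#' pseudo-torsion hold coil segments in helical geometry. Equilibrium
#' values default to the internal coordinates of the ideal C-alpha helix
#' used by the structure builder (see [helix_internal_geometry()]); force
#' constants are chosen so an isolated coil stays helical on the 100 ns
#' scale at 293 K. Linker segments use the *same* equilibrium values but
#' force constants 100-fold weaker, which lets linkers relax out of the
#' initial helix into disordered spacers.
#'
#' @param coil named list with elements `bond = c(r0, k)` (nm, kJ/mol/nm^2),
#'   `angle = c(theta0, k)` (deg, kJ/mol/rad^2),
#'   `torsion = c(phi0, k, mult)` (deg, kJ/mol, integer)
#' @param linker_softening divide coil force constants by this factor to
#'   obtain linker parameters (default 100)
#' @param helix ideal-helix parameters, see [helix_geometry()]
#' @return list with components `coil` and `linker`
#' @export
bonded_params <- function(coil = NULL, linker_softening = 100,
                          helix = helix_geometry()) {
  geom <- helix_internal_geometry(helix)
  if (is.null(coil)) {
    coil <- list(
      bond = c(r0 = geom[["bond"]], k = 8000),
      angle = c(theta0 = geom[["angle"]], k = 200),
      torsion = c(phi0 = geom[["torsion"]], k = 30, mult = 1)
    )
  }
  stopifnot(linker_softening > 0, coil$bond[["k"]] >= 0,
            coil$angle[["k"]] >= 0, coil$torsion[["k"]] >= 0)
  linker <- coil
  linker$bond[["k"]] <- coil$bond[["k"]] / linker_softening
  linker$angle[["k"]] <- coil$angle[["k"]] / linker_softening
  linker$torsion[["k"]] <- coil$torsion[["k"]] / linker_softening
  list(coil = coil, linker = linker)
}

#' Default force field for a multimerization mode
#'
#' Assembles the complete parameter set of the framework: bead classes,
#' bonded parameters with the 100x coil/linker stiffness split, and the
#' nonbonded scheme — truncated-and-shifted Lennard-Jones, cut off at
#' 1.1 nm, with the mode's sticky strength for eligible coil-coil pairs
#' and a small excluded-volume epsilon for everything else.
#'
#' @param mode a [multimer_mode()] or mode name
#' @param cutoff LJ cutoff in nm (default 1.1)
#' @param sigma LJ diameter in nm for all beads (default 0.47)
#' @param eps_rep excluded-volume epsilon in kJ/mol (default 0.1)
#' @param mass bead mass in amu (default 109)
#' @param bonded see [bonded_params()]; `NULL` uses defaults
#' @param helix ideal-helix builder parameters
#' @return object of class `cc_forcefield`
#' @examples
#' ff <- default_forcefield("dimer")
#' ff$mode$epsilon_coil                     # 5.5
#' pair_potential(ff$cutoff, 5.5, ff = ff)  # exactly 0 at the cutoff
#' @export
default_forcefield <- function(mode = "dimer", cutoff = 1.1, sigma = 0.47,
                               eps_rep = 0.1, mass = 109, bonded = NULL,
                               helix = helix_geometry()) {
  if (is.character(mode)) mode <- multimer_mode(mode)
  stopifnot(inherits(mode, "multimer_mode"), cutoff > 0, sigma > 0,
            eps_rep >= 0, mass > 0)
  if (is.null(bonded)) bonded <- bonded_params(helix = helix)
  structure(list(
    mode = mode,
    bead_classes = bead_classes(mass = mass, sigma = sigma,
                                base_epsilon = eps_rep),
    bonded = bonded,
    sigma = sigma,
    eps_rep = eps_rep,
    mass = mass,
    cutoff = cutoff,
    shifted = TRUE,
    helix = helix
  ), class = "cc_forcefield")
}

#' @export
print.cc_forcefield <- function(x, ...) {
  cat(sprintf("cc_forcefield: %s mode, epsilon_coil %g kJ/mol, sigma %g nm, cutoff %g nm (shifted LJ)\n",
              x$mode$name, x$mode$epsilon_coil, x$sigma, x$cutoff))
  cat(sprintf("  coil bond k %g, angle k %g, torsion k %g; linker constants / %g\n",
              x$bonded$coil$bond[["k"]], x$bonded$coil$angle[["k"]],
              x$bonded$coil$torsion[["k"]],
              x$bonded$coil$bond[["k"]] / x$bonded$linker$bond[["k"]]))
  invisible(x)
}

#' Truncated-and-shifted Lennard-Jones pair potential
#'
#' \eqn{V(r) = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6] - V_{cut}} for
#' \eqn{r < r_c} and 0 beyond, where the shift \eqn{V_{cut}} makes the
#' potential exactly zero and continuous at the cutoff.
#'
#' @param r distance(s) in nm
#' @param epsilon well depth in kJ/mol
#' @param sigma LJ diameter in nm
#' @param cutoff cutoff in nm
#' @param shifted shift to zero at the cutoff (default TRUE)
#' @param ff optional `cc_forcefield` supplying sigma/cutoff/shifted
#' @return potential energy in kJ/mol, vectorized over `r`
#' @export
pair_potential <- function(r, epsilon, sigma = 0.47, cutoff = 1.1,
                           shifted = TRUE, ff = NULL) {
  if (!is.null(ff)) {
    sigma <- ff$sigma; cutoff <- ff$cutoff; shifted <- ff$shifted
  }
  stopifnot(all(r > 0))
  lj <- function(x) 4 * epsilon * ((sigma / x)^12 - (sigma / x)^6)
  v <- ifelse(r < cutoff, lj(r) - if (shifted) lj(cutoff) else 0, 0)
  v
}

# ---------------------------------------------------------------------------
# Interaction scheme and pair-eligibility table

#' Interaction scheme
#'
#' Under the maximally specific scheme the only attractive interactions
#' are between sticky beads of coils carrying the same `coil_type_id` on
#' *different* chains; every intrachain sticky-sticky pair is excluded
#' from attraction, and linker beads are always repulsive-only.
#'
#' @param mode currently only `"maximally_specific"`
#' @param allow_intrachain permit intrachain coil-coil attraction
#'   (default FALSE; the framework restricts coil interactions to
#'   interchain contacts)
#' @export
interaction_scheme <- function(mode = "maximally_specific",
                               allow_intrachain = FALSE) {
  mode <- match.arg(mode)
  structure(list(mode = mode, allow_intrachain = isTRUE(allow_intrachain)),
            class = "interaction_scheme")
}

#' Pair-eligibility table for a set of protein specs
#'
#' Enumerates the bead interaction types of the system (`inert` for
#' backbone and linker beads plus one sticky type per `coil_type_id`) and
#' classifies every (type, type, context) combination as `attractive`
#' (with the mode's epsilon) or `repulsive_only` (excluded-volume
#' epsilon). Context is `interchain` or `intrachain`; attraction only
#' ever appears for identical sticky types in the interchain context.
#'
#' @param proteins a [protein_spec()] or list of them
#' @param scheme an [interaction_scheme()]
#' @param ff a [default_forcefield()] parameter set
#' @return data.frame with columns `type_i`, `type_j`, `context`,
#'   `class`, `epsilon`; symmetric in (`type_i`, `type_j`)
#' @export
build_interaction_table <- function(proteins, scheme = interaction_scheme(),
                                    ff = default_forcefield()) {
  if (inherits(proteins, "protein_spec")) proteins <- list(proteins)
  stopifnot(inherits(scheme, "interaction_scheme"),
            inherits(ff, "cc_forcefield"))
  ids <- unlist(lapply(proteins, function(p) {
    vapply(Filter(function(s) s$kind == "coil", p$segments),
           function(s) {
             if (is.null(s$coil_type_id) || !nzchar(s$coil_type_id))
               stop("coil segment missing coil_type_id", call. = FALSE)
             s$coil_type_id
           }, character(1))
  }))
  types <- c("inert", unique(ids))
  grid <- expand.grid(type_i = types, type_j = types,
                      context = c("interchain", "intrachain"),
                      stringsAsFactors = FALSE)
  attractive <- grid$type_i != "inert" & grid$type_i == grid$type_j &
    (grid$context == "interchain" | scheme$allow_intrachain)
  grid$class <- ifelse(attractive, "attractive", "repulsive_only")
  grid$epsilon <- ifelse(attractive, ff$mode$epsilon_coil, ff$eps_rep)
  grid
}
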