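#' Generate a procedural planar dendritic arbor
#'
#' Builds a seeded, radially branching planar morphology standing in for a
#' reconstructed direction-selective ganglion cell: a soma at the origin,
#' `n_primary` primary dendrites radiating outward, and `branch_order`
#' generations of bifurcations. Each branch is a single cylindrical
#' compartment whose proximal end sits at its parent's distal tip. Leaf
#' compartments are labelled `terminal_dendrite` (they carry the synapses
#' and the low active-channel densities), all other dendritic compartments
#' `primary_dendrite`, and the root `soma`.
#'
#' @param arbor_radius_um Radius of the dendritic field (micrometres). All
#'   compartment coordinates are kept within this radius.
#' @param branch_order Number of branch generations (>= 1); 1 gives
#'   unbranched primary dendrites whose tips are terminal.
#' @param n_primary Number of primary dendrites leaving the soma.
#' @param seed Integer seed; the same seed reproduces the arbor exactly.
#' @param soma_diameter_um,primary_diameter_um,terminal_diameter_um
#'   Compartment diameters (micrometres) by region.
#' @param branch_angle_deg Mean angular deviation of daughter branches from
#'   the parent direction at each bifurcation; halved at each generation so
#'   distal branches stay roughly radial.
#' @param length_jitter Relative uniform jitter applied to branch lengths.
#' @return A `morphology` object: a data frame of compartments with columns
#'   `id`, `parent`, `x`, `y` (distal tip, micrometres), `length_um`,
#'   `diameter_um`, `region`, and attribute `arbor_radius_um`.
#' @examples
#' m <- generate_arbor(arbor_radius_um = 150, branch_order = 4, seed = 1)
#' table(m$region)
#' @export
generate_arbor <- function(arbor_radius_um = 150, branch_order = 4,
                           n_primary = 6, seed = 1,
                           soma_diameter_um = 12,
                           primary_diameter_um = 1.5,
                           terminal_diameter_um = 0.7,
                           branch_angle_deg = 40,
                           length_jitter = 0.2) {
  if (arbor_radius_um <= 0) stop("arbor_radius_um must be positive")
  if (branch_order < 1) stop("branch_order must be >= 1")
  if (n_primary < 1) stop("n_primary must be >= 1")

  rng <- local_rng(seed)
  base_len <- arbor_radius_um / branch_order

  id <- 1L
  rows <- list(data.frame(id = 1L, parent = NA_integer_, x = 0, y = 0,
                          length_um = soma_diameter_um,
                          diameter_um = soma_diameter_um,
                          region = "soma", stringsAsFactors = FALSE))
  # frontier: one entry per growing branch tip
  frontier <- data.frame(
    parent = 1L, x = 0, y = 0,
    angle = 360 * (seq_len(n_primary) - 1) / n_primary +
      rng$runif(n_primary, -0.15, 0.15) * 360 / n_primary,
    order = 1L
  )

  while (nrow(frontier) > 0) {
    nxt <- list()
    for (k in seq_len(nrow(frontier))) {
      f <- frontier[k, ]
      len <- base_len * (1 + rng$runif(1, -length_jitter, length_jitter))
      th <- f$angle * pi / 180
      x1 <- f$x + len * cos(th)
      y1 <- f$y + len * sin(th)
      r1 <- sqrt(x1^2 + y1^2)
      if (r1 > arbor_radius_um) {          # clip tip to the dendritic field
        scl <- arbor_radius_um / r1
        x1 <- x1 * scl; y1 <- y1 * scl
        len <- sqrt((x1 - f$x)^2 + (y1 - f$y)^2)
      }
      id <- id + 1L
      terminal <- f$order >= branch_order
      rows[[length(rows) + 1L]] <- data.frame(
        id = id, parent = f$parent, x = x1, y = y1, length_um = len,
        diameter_um = if (terminal) terminal_diameter_um else primary_diameter_um,
        region = if (terminal) "terminal_dendrite" else "primary_dendrite",
        stringsAsFactors = FALSE)
      if (!terminal) {
        spread <- branch_angle_deg / 2^(f$order - 1)
        for (s in c(-1, 1)) {
          nxt[[length(nxt) + 1L]] <- data.frame(
            parent = id, x = x1, y = y1,
            angle = f$angle + s * spread * rng$runif(1, 0.7, 1.3),
            order = f$order + 1L)
        }
      }
    }
    frontier <- if (length(nxt)) do.call(rbind, nxt) else frontier[0, ]
  }

  m <- do.call(rbind, rows)
  rownames(m) <- NULL
  attr(m, "arbor_radius_um") <- arbor_radius_um
  class(m) <- c("morphology", class(m))
  validate_morphology(m)
  m
}

#' Validate a morphology's structural invariants
#'
#' Checks that there is exactly one soma root, that the parent graph is a
#' tree, that terminal-dendrite compartments have no children, and that all
#' dendritic coordinates lie within the arbor radius.
#'
#' @param m A `morphology` object.
#' @return `m`, invisibly; stops with an informative error on violation.
#' @export
validate_morphology <- function(m) {
  stopifnot(is.data.frame(m))
  roots <- which(is.na(m$parent))
  if (length(roots) != 1L || m$region[roots] != "soma")
    stop("morphology must have exactly one soma root")
  if (!all(m$parent[-roots] %in% m$id))
    stop("dangling parent reference")
  # tree check: every compartment must reach the root without revisiting
  idx <- match(m$parent, m$id)
  for (i in seq_len(nrow(m))) {
    seen <- logical(nrow(m)); j <- i
    while (!is.na(idx[j])) {
      if (seen[j]) stop("cycle detected in parent graph")
      seen[j] <- TRUE
      j <- idx[j]
    }
  }
  has_child <- m$id %in% m$parent
  if (any(has_child & m$region == "terminal_dendrite"))
    stop("terminal_dendrite compartments must have no children")
  r <- sqrt(m$x^2 + m$y^2)
  if (any(r > attr(m, "arbor_radius_um") + 1e-9))
    stop("dendritic coordinates outside arbor radius")
  invisible(m)
}

#' @export
print.morphology <- function(x, ...) {
  cat(sprintf("<morphology> %d compartments (radius %g um): %s\n",
              nrow(x), attr(x, "arbor_radius_um"),
              paste(sprintf("%s=%d", names(table(x$region)),
                            as.integer(table(x$region))), collapse = ", ")))
  invisible(x)
}

#' Default tri-receptor kinetic specification
#'
#' Every synapse site carries one receptor entry per transmitter: AMPA
#' (glutamate), nicotinic (acetylcholine) and GABA-A (GABA). Kinetics are
#' bi-exponential (rise < decay, milliseconds); peak conductances are in
#' nanosiemens and reversal potentials in millivolts. The defaults are
#' calibrated so that a moving bar releasing glutamate and acetylcholine at
#' roughly half the sites drives somatic spiking, while temporally
#' coincident GABA (a strong, slowly decaying shunt at the leak reversal)
#' suppresses it; evoked inhibition in these cells long outlasts the
#' underlying miniature-event kinetics.
#'
#' @param glutamate,acetylcholine,gaba Named lists with fields `rise_ms`,
#'   `decay_ms`, `gpeak_ns`, `e_rev_mv` overriding the defaults.
#' @return A named list of per-transmitter receptor specs.
#' @export
receptor_defaults <- function(glutamate = list(), acetylcholine = list(),
                              gaba = list()) {
  merge_spec <- function(base, user) {
    base[names(user)] <- user
    if (base$rise_ms >= base$decay_ms) stop("receptor rise must be < decay")
    if (base$gpeak_ns < 0) stop("peak conductance must be >= 0")
    base
  }
  list(
    glutamate = merge_spec(
      list(rise_ms = 0.2, decay_ms = 2, gpeak_ns = 0.45, e_rev_mv = 0),
      glutamate),
    acetylcholine = merge_spec(
      list(rise_ms = 2, decay_ms = 25, gpeak_ns = 0.2, e_rev_mv = 0),
      acetylcholine),
    gaba = merge_spec(
      list(rise_ms = 0.5, decay_ms = 30, gpeak_ns = 4, e_rev_mv = -60),
      gaba)
  )
}

#' Place tri-receptor synapse sites on terminal dendrites
#'
#' Distributes synapse sites along every terminal-dendrite branch at
#' approximately `target_spacing_um` intervals (each branch receives
#' `max(1, round(length / spacing))` sites at its interior quantile
#' positions, so realised spacing stays within +/-50 percent of the
#' target). Each site carries the full tri-receptor kinetic specification.
#'
#' @param morphology A `morphology` object.
#' @param target_spacing_um Target inter-site spacing along a branch
#'   (micrometres, > 0).
#' @param seed Integer seed (reserved for jittered placement variants; the
#'   default quantile rule is deterministic).
#' @param receptors Receptor specification, see [receptor_defaults()].
#' @return A `synapse_sites` data frame with columns `site_id`,
#'   `compartment_id`, `x`, `y`, and the receptor list as attribute
#'   `receptors`. Zero rows (with a warning) if the arbor has no terminal
#'   compartments.
#' @export
place_synapses <- function(morphology, target_spacing_um = 5, seed = 1,
                           receptors = receptor_defaults()) {
  validate_morphology(morphology)
  if (target_spacing_um <= 0) stop("target_spacing_um must be positive")
  term <- morphology[morphology$region == "terminal_dendrite", , drop = FALSE]
  if (nrow(term) == 0L) {
    warning("morphology has no terminal_dendrite compartments; no synapses placed")
    out <- data.frame(site_id = integer(), compartment_id = integer(),
                      x = numeric(), y = numeric())
    attr(out, "receptors") <- receptors
    class(out) <- c("synapse_sites", class(out))
    return(out)
  }
  pidx <- match(term$parent, morphology$id)
  rows <- vector("list", nrow(term))
  for (k in seq_len(nrow(term))) {
    x0 <- morphology$x[pidx[k]]; y0 <- morphology$y[pidx[k]]
    x1 <- term$x[k]; y1 <- term$y[k]
    n <- max(1L, as.integer(round(term$length_um[k] / target_spacing_um)))
    fr <- (seq_len(n) - 0.5) / n
    rows[[k]] <- data.frame(compartment_id = term$id[k],
                            x = x0 + fr * (x1 - x0),
                            y = y0 + fr * (y1 - y0))
  }
  out <- do.call(rbind, rows)
  out <- data.frame(site_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "receptors") <- receptors
  class(out) <- c("synapse_sites", class(out))
  out
}

#' @export
print.synapse_sites <- function(x, ...) {
  cat(sprintf("<synapse_sites> %d sites on %d terminal compartments\n",
              nrow(x), length(unique(x$compartment_id))))
  invisible(x)
}

# Seed-local RNG helper: draws from an isolated RNG stream so package
# functions never disturb the caller's .Random.seed.
local_rng <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  draw <- function(fun, ...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- fun(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
  list(
    runif = function(n, min = 0, max = 1) draw(stats::runif, n, min, max),
    rnorm = function(n, mean = 0, sd = 1) draw(stats::rnorm, n, mean, sd),
    rpois = function(n, lambda) draw(stats::rpois, n, lambda),
    int = function(n = 1, max = .Machine$integer.max)
      draw(function(n) as.integer(floor(stats::runif(n, 0, max))), n)
  )
}
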