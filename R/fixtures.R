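#' Deterministic toy molecules
#'
#' Built-in rigid-molecule fixtures so every pipeline stage can be
#' exercised without external structures: a single LJ sphere, a charged
#' two-residue dumbbell, and a four-atom two-residue "mini protein".
#'
#' @param kind `"sphere"`, `"charged_dumbbell"` or `"tetramer"`.
#' @param lj_sigma self-pair LJ sigma (Angstrom); the hard-core radius is
#'   `lj_sigma/2`.
#' @param lj_epsilon LJ well depth (kcal/mol).
#' @param charge sphere charge, or dumbbell charge magnitude (+q/-q), e.
#' @param separation dumbbell bond length / tetramer edge scale, Angstrom.
#' @return a [rigid_molecule()].
#' @export
make_toy <- function(kind = c("sphere", "charged_dumbbell", "tetramer"),
                     lj_sigma = 4, lj_epsilon = 0.2, charge = 0,
                     separation = 5) {
  kind <- match.arg(kind)
  atom <- function(serial, name, resname, ri, x, y, z, q) {
    data.frame(serial = serial, name = name, residue_name = resname,
               residue_index = ri, chain = "A", x = x, y = y, z = z,
               charge = q, lj_epsilon = lj_epsilon, lj_sigma = lj_sigma,
               stringsAsFactors = FALSE)
  }
  atoms <- switch(kind,
    sphere = atom(1L, "C1", "SPH", 1L, 0, 0, 0, charge),
    charged_dumbbell = rbind(
      atom(1L, "C1", "DUM", 1L, 0, 0, -separation / 2, +charge),
      atom(2L, "C2", "DUM", 2L, 0, 0, +separation / 2, -charge)
    ),
    tetramer = rbind(
      atom(1L, "C1", "TTA", 1L, 0, 0, 0, +charge),
      atom(2L, "C2", "TTA", 1L, separation, 0, 0, -charge),
      atom(3L, "C3", "TTB", 2L, 0, separation, 0, +charge),
      atom(4L, "C4", "TTB", 2L, 0, 0, separation, -charge)
    )
  )
  rigid_molecule(atoms, label = kind)
}
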