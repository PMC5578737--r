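#' Helical wheel window
#'
#' A residue window of a transmembrane helix projected onto a wheel: residue
#' `i` sits at angle `(i - start_position) * angle_step_deg mod 360`, with
#' the default 100 degrees per residue of an ideal alpha-helix (3.6
#' residues per turn).
#'
#' @param sequence one-letter residue string (standard 20 amino acids).
#' @param start_position residue number of the first letter.
#' @param angle_step_deg rotation per residue, in the open interval
#'   `(0, 360)`.
#' @return object of class `helix_window`.
#' @export
helix_window <- function(sequence, start_position, angle_step_deg = 100) {
  residues <- strsplit(toupper(sequence), "")[[1]]
  if (length(residues) == 0L)
    stop_tim23("sequence must be non-empty", "tim23_invalid_window")
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  bad <- setdiff(residues, aa)
  if (length(bad))
    stop_tim23(paste("invalid residue letter(s):",
                     paste(unique(bad), collapse = ", ")),
               "tim23_invalid_residue")
  if (angle_step_deg <= 0 || angle_step_deg >= 360)
    stop_tim23("angle_step_deg must lie strictly inside (0, 360)",
               "tim23_invalid_window")
  structure(list(residues = residues,
                 start_position = as.integer(start_position),
                 angle_step_deg = angle_step_deg),
            class = "helix_window")
}

#' Wheel angles of a helix window
#'
#' @param window a [helix_window()].
#' @return data.frame with `position`, `residue`, `angle_deg` in `[0, 360)`.
#' @export
wheel_angles <- function(window) {
  stopifnot(inherits(window, "helix_window"))
  pos <- window$start_position + seq_along(window$residues) - 1L
  data.frame(position = pos, residue = window$residues,
             angle_deg = ((pos - window$start_position) *
                            window$angle_step_deg) %% 360)
}

#' Default polar residue classification
#'
#' Charged and polar side chains (D, E, K, R, H, N, Q, S, T, Y, C); glycine
#' is treated as neutral and excluded. Exposed so the classification can be
#' swapped.
#' @export
polar_residues_default <- c("D", "E", "K", "R", "H", "N", "Q", "S", "T",
                            "Y", "C")

#' Polar/apolar face assignment on a helical wheel
#'
#' Tags each residue by membership in `polar_set` and reports the mean
#' direction of the polar residues (the argument of the vector sum of unit
#' vectors at their wheel angles); the direction is flagged undefined when
#' the polar residues cancel (resultant near zero).
#'
#' @param window a [helix_window()].
#' @param polar_set residues classified as polar.
#' @return list with `residues` (data.frame: position, residue, angle_deg,
#'   face), `polar_direction_deg` (`NA` when undefined),
#'   `polar_resultant` (length of the polar vector sum) and
#'   `direction_defined`.
#' @export
face_assignment <- function(window, polar_set = polar_residues_default) {
  tab <- wheel_angles(window)
  tab$face <- ifelse(tab$residue %in% polar_set, "polar", "apolar")
  ang <- tab$angle_deg[tab$face == "polar"] * pi / 180
  vx <- sum(cos(ang)); vy <- sum(sin(ang))
  resultant <- sqrt(vx^2 + vy^2)
  defined <- length(ang) > 0 && resultant > 1e-8
  list(residues = tab,
       polar_direction_deg = if (defined) (atan2(vy, vx) * 180 / pi) %% 360
                             else NA_real_,
       polar_resultant = resultant,
       direction_defined = defined)
}

#' Kyte-Doolittle hydropathy scale
#' @export
kyte_doolittle <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Hydrophobic moment of a helix window
#'
#' Vector sum of per-residue hydrophobicity times the unit vector at the
#' residue's wheel angle; the quantitative companion to a qualitative
#' polar/apolar hemisphere plot. The magnitude is invariant under a global
#' rotation of the wheel.
#'
#' @param window a [helix_window()].
#' @param scale named numeric hydrophobicity per residue (default
#'   [kyte_doolittle]).
#' @return list with `magnitude` and `direction_deg` (`NA` when the moment
#'   is ~0).
#' @export
hydrophobic_moment <- function(window, scale = kyte_doolittle) {
  tab <- wheel_angles(window)
  missing <- setdiff(tab$residue, names(scale))
  if (length(missing))
    stop_tim23(paste("residue(s) missing from scale:",
                     paste(unique(missing), collapse = ", ")),
               "tim23_invalid_residue")
  h <- scale[tab$residue]
  ang <- tab$angle_deg * pi / 180
  vx <- sum(h * cos(ang)); vy <- sum(h * sin(ang))
  mag <- sqrt(vx^2 + vy^2)
  list(magnitude = mag,
       direction_deg = if (mag > 1e-8) (atan2(vy, vx) * 180 / pi) %% 360
                       else NA_real_)
}
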