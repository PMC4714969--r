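# Equivalent-circuit model of an ependymal cell accessed through a motile
# cilium. The cilium is treated as a lumped access (series) resistor in front
# of the parallel R_m/C_m of the cell membrane; all derived-quantity formulas
# used elsewhere in the package live here.

#' Cilium geometry
#'
#' A motile cilium idealised as a cylinder. Lengths in micrometres.
#' Defaults correspond to a typical ependymal motile cilium: length 11.5 um,
#' diameter 0.25 um.
#'
#' @param length_um Cilium length (height of the cylinder), um. Must be > 0.
#' @param radius_um Cilium radius, um. Must be > 0 and < length.
#' @return Object of class `cilium_geometry`.
#' @export
cilium_geometry <- function(length_um = 11.5, radius_um = 0.125) {
  stopifnot_positive(length_um = length_um, radius_um = radius_um)
  if (radius_um >= length_um) {
    stop("`radius_um` must be smaller than `length_um` for a cilium-like cylinder",
         call. = FALSE)
  }
  structure(list(length_um = length_um, radius_um = radius_um),
            class = "cilium_geometry")
}

#' Membrane and cytoplasm constants
#'
#' Specific membrane capacitance (biological membranes are close to
#' 1 uF/cm^2), internal (axial) resistivity, and recording temperature.
#' Axial resistivity defaults to 150 Ohm cm, a cytoplasm-like value; the true
#' internal resistivity of a motile cilium is not known, so it is kept as a
#' free parameter.
#'
#' @param spec_cap_uF_cm2 Specific capacitance, uF/cm^2.
#' @param rho_ohm_cm Axial resistivity, Ohm cm.
#' @param temperature_C Temperature, degrees Celsius (room temperature default).
#' @return Object of class `membrane_constants`.
#' @export
membrane_constants <- function(spec_cap_uF_cm2 = 1, rho_ohm_cm = 150,
                               temperature_C = 22) {
  stopifnot_positive(spec_cap_uF_cm2 = spec_cap_uF_cm2, rho_ohm_cm = rho_ohm_cm)
  if (!is.finite(temperature_C) || temperature_C <= -273.15) {
    stop("`temperature_C` must be above absolute zero", call. = FALSE)
  }
  structure(list(spec_cap_uF_cm2 = spec_cap_uF_cm2, rho_ohm_cm = rho_ohm_cm,
                 temperature_C = temperature_C),
            class = "membrane_constants")
}

#' Equivalent circuit of a patched cell
#'
#' Lumped circuit seen by the amplifier: a series (access) resistance
#' `r_series_MOhm` (pipette plus ciliary cable in the whole-motile-cilium
#' configuration) in front of membrane capacitance `c_m_pF` in parallel with
#' membrane (leak) resistance `r_m_MOhm`. `r_m_MOhm = Inf` encodes an ideally
#' leak-free membrane.
#'
#' @param c_m_pF Membrane capacitance, pF.
#' @param r_series_MOhm Access/series resistance, MOhm.
#' @param r_m_MOhm Membrane resistance, MOhm; may be `Inf`.
#' @param v_hold_mV Holding potential, mV.
#' @return Object of class `equivalent_circuit`.
#' @export
equivalent_circuit <- function(c_m_pF, r_series_MOhm, r_m_MOhm = Inf,
                               v_hold_mV = -80) {
  stopifnot_positive(c_m_pF = c_m_pF, r_series_MOhm = r_series_MOhm)
  if (!(is.infinite(r_m_MOhm) || (is.finite(r_m_MOhm) && r_m_MOhm > 0))) {
    stop("`r_m_MOhm` must be positive or Inf", call. = FALSE)
  }
  structure(list(c_m_pF = c_m_pF, r_series_MOhm = r_series_MOhm,
                 r_m_MOhm = r_m_MOhm, v_hold_mV = v_hold_mV),
            class = "equivalent_circuit")
}

#' @export
print.equivalent_circuit <- function(x, ...) {
  cat(sprintf(
    "Equivalent circuit: C_m = %.3g pF, R_series = %.3g MOhm, R_m = %.3g MOhm, V_hold = %g mV\n",
    x$c_m_pF, x$r_series_MOhm, x$r_m_MOhm, x$v_hold_mV))
  cat(sprintf("  clamp time constant: %.3g ms\n", clamp_time_constant(x)))
  invisible(x)
}

#' Surface area of a cylindrical cilium
#'
#' A = 2 pi r (r + h): lateral wall plus the two end disks. For the default
#' ependymal cilium (r = 0.125 um, h = 11.5 um) this is ~9.1 um^2.
#'
#' @param geom A [cilium_geometry()].
#' @return Surface area in um^2.
#' @examples
#' cylinder_surface_area(cilium_geometry(11.5, 0.125))  # ~9.13
#' @export
cylinder_surface_area <- function(geom) {
  stopifnot(inherits(geom, "cilium_geometry"))
  2 * pi * geom$radius_um * (geom$radius_um + geom$length_um)
}

#' Membrane capacitance from surface area
#'
#' Converts a membrane area to capacitance at a given specific capacitance.
#' At 1 uF/cm^2 (= 0.01 pF/um^2) the ~9.1 um^2 cilium carries ~0.091 pF.
#'
#' @param area_um2 Membrane area, um^2 (>= 0).
#' @param constants A [membrane_constants()].
#' @return Capacitance in pF.
#' @export
membrane_capacitance_from_area <- function(area_um2,
                                           constants = membrane_constants()) {
  if (!is.numeric(area_um2) || any(area_um2 < 0)) {
    stop("`area_um2` must be non-negative", call. = FALSE)
  }
  # 1 uF/cm^2 = 0.01 pF/um^2
  area_um2 * constants$spec_cap_uF_cm2 * 0.01
}

#' Axial cable resistance of a cilium
#'
#' R = rho * l / A with A = pi r^2 the cross-sectional area: the resistance
#' of the ciliary lumen treated as an ideally insulated ohmic cable. With
#' rho = 150 Ohm cm, l = 11.5 um, r = 0.125 um this gives ~350 MOhm.
#'
#' @param geom A [cilium_geometry()], or a list with `length_um`, `radius_um`
#'   (so a zero-length degenerate cable can be evaluated).
#' @param constants A [membrane_constants()] supplying `rho_ohm_cm`.
#' @return Resistance in MOhm.
#' @examples
#' cable_resistance(cilium_geometry(11.5, 0.125))  # ~351.4 MOhm
#' @export
cable_resistance <- function(geom, constants = membrane_constants()) {
  l <- geom$length_um; r <- geom$radius_um
  if (!is.numeric(l) || l < 0) stop("length must be >= 0", call. = FALSE)
  if (!is.numeric(r) || r <= 0) stop("radius must be > 0", call. = FALSE)
  u <- unit_factors()
  rho_SI <- constants$rho_ohm_cm * u[["ohm_cm"]]        # Ohm m
  area_SI <- pi * (r * u[["um"]])^2                     # m^2
  (rho_SI * l * u[["um"]] / area_SI) / u[["MOhm"]]
}

#' Total number of channels per cell
#'
#' N = I_m / (P_o * i): mean peak whole-cell current divided by the product of
#' single-channel open probability and unitary amplitude. `I_m` and `i_single`
#' must carry the same sign (both inward or both outward).
#'
#' @param i_m_pA Mean peak whole-cell current at the reference voltage, pA.
#' @param p_open Single-channel open probability, in (0, 1].
#' @param i_single_pA Single-channel amplitude at the same voltage, pA (non-zero).
#' @return Estimated channel count (real-valued; rounding is the caller's choice).
#' @examples
#' channels_per_cell(297.8, 0.32, 1.4)  # ~664.7
#' @export
channels_per_cell <- function(i_m_pA, p_open, i_single_pA) {
  if (!is.numeric(p_open) || p_open <= 0 || p_open > 1) {
    stop("`p_open` must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(i_single_pA) || i_single_pA == 0) {
    stop("`i_single_pA` must be non-zero", call. = FALSE)
  }
  if (i_m_pA != 0 && sign(i_m_pA) != sign(i_single_pA)) {
    stop("`i_m_pA` and `i_single_pA` must have the same sign", call. = FALSE)
  }
  i_m_pA / (p_open * i_single_pA)
}

#' Expected number of channels in one cilium
#'
#' Scales the per-cell channel count by the cilium-to-cell membrane-area
#' ratio, expressed as the capacitance ratio (capacitance is proportional to
#' area at fixed specific capacitance). With 664.7 channels/cell, 0.091 pF
#' cilium and 18.5 pF cell this is ~3 channels.
#'
#' @param n_cell Channel count for the whole cell.
#' @param c_cilium_pF Cilium membrane capacitance, pF.
#' @param c_cell_pF Whole-cell membrane capacitance, pF (> c_cilium_pF).
#' @return Expected channel count in the cilium (real-valued).
#' @export
channels_per_cilium <- function(n_cell, c_cilium_pF, c_cell_pF) {
  stopifnot_positive(c_cell_pF = c_cell_pF)
  if (c_cilium_pF < 0) stop("`c_cilium_pF` must be >= 0", call. = FALSE)
  if (c_cilium_pF > c_cell_pF) {
    stop("`c_cilium_pF` cannot exceed `c_cell_pF`", call. = FALSE)
  }
  n_cell * c_cilium_pF / c_cell_pF
}

#' Actual membrane voltage under series-resistance error
#'
#' V_m = V_command - I_m * R_series. With the inward-negative sign convention
#' an inward current makes the membrane more positive than the command, the
#' classical series-resistance voltage error.
#'
#' @param v_command_mV Command voltage, mV.
#' @param i_m_pA Membrane current, pA (inward negative).
#' @param r_series_MOhm Series resistance, MOhm.
#' @return Membrane voltage, mV.
#' @examples
#' membrane_voltage(0, -300, 180)  # +54 mV
#' @export
membrane_voltage <- function(v_command_mV, i_m_pA, r_series_MOhm) {
  # pA * MOhm = uV; /1000 -> mV
  v_command_mV - i_m_pA * r_series_MOhm / 1000
}

#' Voltage-clamp charging time constant
#'
#' Full model: tau = C_m * (R_series * R_m)/(R_series + R_m), i.e. the
#' capacitance sees the parallel combination of access and membrane
#' resistance. As R_m -> Inf this reduces to the familiar tau = R_series C_m.
#'
#' @param circuit An [equivalent_circuit()].
#' @param ideal If `TRUE`, return the R_m -> Inf form R_series*C_m regardless
#'   of the circuit's R_m.
#' @return Time constant in ms.
#' @examples
#' clamp_time_constant(equivalent_circuit(18.5, 180))  # 3.33 ms
#' @export
clamp_time_constant <- function(circuit, ideal = FALSE) {
  r_eff <- if (ideal || is.infinite(circuit$r_m_MOhm)) {
    circuit$r_series_MOhm
  } else {
    circuit$r_series_MOhm * circuit$r_m_MOhm /
      (circuit$r_series_MOhm + circuit$r_m_MOhm)
  }
  # MOhm * pF = us; /1000 -> ms
  r_eff * circuit$c_m_pF / 1000
}

#' Nernst equilibrium potential
#'
#' E = (RT / zF) ln([out]/[in]) for an ion of valence z, reported in mV.
#' RT/F is evaluated from physical constants at the supplied temperature.
#'
#' @param ion_out_mM Extracellular concentration, mM (> 0).
#' @param ion_in_mM Intracellular concentration, mM (> 0).
#' @param valence Ion valence (non-zero integer); +1 for K+.
#' @param temperature_C Temperature in Celsius.
#' @return Equilibrium potential, mV.
#' @examples
#' nernst_potential(3, 130.5)  # E_K in 3 mM external K+, ~-96 mV
#' @export
nernst_potential <- function(ion_out_mM, ion_in_mM, valence = 1L,
                             temperature_C = 22) {
  stopifnot_positive(ion_out_mM = ion_out_mM, ion_in_mM = ion_in_mM)
  if (valence == 0) stop("`valence` must be non-zero", call. = FALSE)
  T_K <- temperature_C + 273.15
  (.GAS_CONSTANT * T_K / (valence * .FARADAY)) * log(ion_out_mM / ion_in_mM) * 1000
}

#' Derived circuit quantities for a cilium-accessed cell
#'
#' Convenience wrapper collecting every derived quantity in one data frame:
#' cilium surface area and capacitance, axial cable resistance, clamp time
#' constant, and (when whole-cell current statistics are supplied) channel
#' counts per cell and per cilium.
#'
#' @param geom A [cilium_geometry()].
#' @param constants A [membrane_constants()].
#' @param circuit Optional [equivalent_circuit()] for the tau row.
#' @param i_m_pA,p_open,i_single_pA Optional channel-count inputs
#'   (see [channels_per_cell()]).
#' @param c_cell_pF Whole-cell capacitance used for the per-cilium scaling, pF.
#' @return data.frame with columns `quantity`, `value`, `unit`.
#' @export
derive_circuit_quantities <- function(geom = cilium_geometry(),
                                      constants = membrane_constants(),
                                      circuit = NULL,
                                      i_m_pA = NULL, p_open = NULL,
                                      i_single_pA = NULL, c_cell_pF = 18.5) {
  area <- cylinder_surface_area(geom)
  c_cil <- membrane_capacitance_from_area(area, constants)
  out <- data.frame(
    quantity = c("cilium_surface_area", "cilium_capacitance", "cable_resistance"),
    value = c(area, c_cil, cable_resistance(geom, constants)),
    unit = c("um^2", "pF", "MOhm"),
    stringsAsFactors = FALSE
  )
  if (!is.null(circuit)) {
    out <- rbind(out, data.frame(quantity = "clamp_time_constant",
                                 value = clamp_time_constant(circuit),
                                 unit = "ms"))
  }
  if (!is.null(i_m_pA) && !is.null(p_open) && !is.null(i_single_pA)) {
    n_cell <- channels_per_cell(i_m_pA, p_open, i_single_pA)
    out <- rbind(out,
      data.frame(quantity = c("channels_per_cell", "channels_per_cilium"),
                 value = c(n_cell, channels_per_cilium(n_cell, c_cil, c_cell_pF)),
                 unit = c("count", "count")))
  }
  out
}
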