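# Physical constants and geometry shared across modules.
# Internal length unit is the micrometre; times are seconds; energies eV.

.AVOGADRO  <- 6.02214076e23      # mol^-1
.EV_JOULE  <- 1.602176634e-19    # J per eV
.P_ATM     <- 760                # mmHg
.HENRY_O2  <- 1.26               # uM per mmHg, Henry coefficient for O2 in water

# Phantom: [0, 2]^3 um cube; irradiation volume (IV): central [0.5, 1.5]^3 um.
.BOX_L     <- 2
.IV_LO     <- 0.5
.IV_HI     <- 1.5
.IV_VOLUME_UM3 <- 1
.IV_MASS_KG    <- 1e-15          # 1 um^3 of unit-density water

# 1 molecule in 1 um^3 expressed as a molar concentration (M) and in uM
.MOLEC_PER_UM3_M  <- 1 / (.AVOGADRO * 1e-15)
.MOLEC_PER_UM3_UM <- .MOLEC_PER_UM3_M * 1e6

#' Convert an oxygen partial pressure in percent to a molar concentration
#'
#' Dissolved oxygen is specified as a percentage of atmospheric pressure
#' (760 mmHg) and converted to micromolar via Henry's law for O2 in liquid
#' water (1.26 uM/mmHg), so 25\% corresponds to 239.4 uM.
#'
#' @param pO2_percent partial pressure of O2 as a percentage of 760 mmHg.
#' @return concentration in uM.
#' @export
#' @examples
#' pO2_to_uM(25) # 239.4
pO2_to_uM <- function(pO2_percent) {
  stopifnot(is.numeric(pO2_percent), all(pO2_percent >= 0))
  pO2_percent * .P_ATM * .HENRY_O2 / 100
}

#' Convert an oxygen concentration in uM back to percent of atmosphere
#' @param uM concentration in uM.
#' @return partial pressure as percent of 760 mmHg.
#' @export
uM_to_pO2 <- function(uM) {
  stopifnot(is.numeric(uM), all(uM >= 0))
  uM * 100 / (.P_ATM * .HENRY_O2)
}
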