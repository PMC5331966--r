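#' Antiretroviral drug vocabulary
#'
#' Canonical compound identities with their pharmacologic type, used by the
#' regimen classifier. Types: `nrti` (nucleoside/nucleotide backbone drugs),
#' `pi` (protease inhibitors), `nnrti`, `insti` (integrase inhibitors) and
#' `booster` (ritonavir, counted purely as a pharmacokinetic booster and
#' never as an anchor by itself).
#'
#' @return data.table with columns `compound`, `arv_type`.
#' @export
arv_vocabulary <- function() {
  data.table::data.table(
    compound = c("tenofovir", "abacavir", "zidovudine", "lamivudine",
                 "emtricitabine", "stavudine", "didanosine",
                 "efavirenz", "nevirapine",
                 "darunavir", "atazanavir", "lopinavir", "indinavir",
                 "raltegravir", "dolutegravir",
                 "ritonavir"),
    arv_type = c(rep("nrti", 7), rep("nnrti", 2), rep("pi", 4),
                 rep("insti", 2), "booster"))
}

arv_types <- function(arvs) {
  voc <- arv_vocabulary()
  voc$arv_type[match(arvs, voc$compound)]
}

#' Classify the anchor-drug component of an active ARV set
#'
#' Anchor drugs are all ARVs that are not NRTIs; ritonavir is a booster, not
#' an anchor. Categories are mutually exclusive, assigned in priority order:
#' \describe{
#'   \item{modern}{efavirenz, ritonavir-boosted darunavir, or an integrase
#'     inhibitor}
#'   \item{boosted_pi_other}{a ritonavir-boosted PI other than darunavir}
#'   \item{unboosted_nvp_other}{any other anchor (unboosted PI, nevirapine,
#'     or other)}
#'   \item{none}{no anchor drug active}
#' }
#'
#' @param arvs character vector of active compound identities (see
#'   [arv_vocabulary()]).
#' @return one of `"modern"`, `"boosted_pi_other"`, `"unboosted_nvp_other"`,
#'   `"none"`.
#' @export
classify_anchor <- function(arvs) {
  arvs <- unique(arvs)
  ty <- arv_types(arvs)
  boosted <- "ritonavir" %in% arvs
  if ("efavirenz" %in% arvs || any(ty == "insti", na.rm = TRUE) ||
      (boosted && "darunavir" %in% arvs)) return("modern")
  pis_other <- arvs[!is.na(ty) & ty == "pi" & arvs != "darunavir"]
  if (boosted && length(pis_other)) return("boosted_pi_other")
  anchors <- arvs[!is.na(ty) & !ty %in% c("nrti", "booster")]
  if (length(anchors)) return("unboosted_nvp_other")
  "none"
}

#' Classify the NRTI component of an active ARV set
#'
#' Returns the set of complementary (non-exclusive) NRTI exposure categories:
#' `tenofovir`, `lamivudine_emtricitabine` (lamivudine or emtricitabine),
#' `other` (any other NRTI), or `none` if no NRTI is active.
#'
#' @inheritParams classify_anchor
#' @return character vector of categories; `"none"` alone iff no NRTI.
#' @export
classify_nrti <- function(arvs) {
  arvs <- unique(arvs)
  ty <- arv_types(arvs)
  nrtis <- arvs[!is.na(ty) & ty == "nrti"]
  if (!length(nrtis)) return("none")
  out <- character(0)
  if ("tenofovir" %in% nrtis) out <- c(out, "tenofovir")
  if (any(c("lamivudine", "emtricitabine") %in% nrtis))
    out <- c(out, "lamivudine_emtricitabine")
  if (length(setdiff(nrtis, c("tenofovir", "lamivudine", "emtricitabine"))))
    out <- c(out, "other")
  out
}

#' Does an active ARV set constitute HAART?
#'
#' True iff any of four rules holds:
#' (1) at least one anchor drug with at least two NRTIs;
#' (2) triple-class therapy, interpreted as at least one NRTI plus at least
#' one PI plus at least one NNRTI concurrently;
#' (3) a ritonavir-boosted PI plus an NNRTI;
#' (4) triple-NRTI therapy containing (tenofovir or abacavir) and zidovudine
#' and (lamivudine or emtricitabine).
#' The predicate is monotone: adding a drug never revokes HAART status.
#'
#' @inheritParams classify_anchor
#' @return logical flag.
#' @export
is_haart <- function(arvs) {
  arvs <- unique(arvs)
  ty <- arv_types(arvs)
  nrtis <- arvs[!is.na(ty) & ty == "nrti"]
  anchors <- arvs[!is.na(ty) & !ty %in% c("nrti", "booster")]
  has_pi <- any(ty == "pi", na.rm = TRUE)
  has_nnrti <- any(ty == "nnrti", na.rm = TRUE)
  bpi <- has_pi && "ritonavir" %in% arvs
  d1 <- length(anchors) >= 1L && length(nrtis) >= 2L
  d2 <- length(nrtis) >= 1L && has_pi && has_nnrti
  d3 <- bpi && has_nnrti
  d4 <- any(c("tenofovir", "abacavir") %in% nrtis) &&
    "zidovudine" %in% nrtis &&
    any(c("lamivudine", "emtricitabine") %in% nrtis)
  d1 || d2 || d3 || d4
}
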