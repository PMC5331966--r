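#' Default drug-to-class mapping
#'
#' Maps each drug code to exactly one exposure class label. Medication
#' classes: `statin`, `ALP` (non-statin lipid-lowering), `AHT`
#' (antihypertensive), `ASA` (cardio-protective aspirin). Antiretrovirals
#' carry a subtype: NRTIs map to the complementary exposure categories
#' (`tenofovir`, `lamivudine_emtricitabine`, `other`) and anchor drugs to the
#' mutually exclusive categories (`modern`, `boosted_pi_other`,
#' `unboosted_or_nvp_other`). Ritonavir is mapped to its own `booster` class:
#' it is a pharmacokinetic booster, not an anchor, and giving it its own
#' label keeps a co-dispensed PI's supply from being discarded as a
#' same-class therapy switch. Darunavir is carried under the modern-anchor
#' label (it is dispensed ritonavir-boosted in practice); exact drug-level
#' anchor classification for arbitrary combinations is provided by
#' [classify_anchor()].
#'
#' @return data.table with `drug_code`, `class`, `subtype`.
#' @export
default_drug_class_map <- function() {
  data.table::rbindlist(list(
    data.table::data.table(
      drug_code = c("pravastatin", "simvastatin", "fluvastatin",
                    "rosuvastatin", "atorvastatin", "lovastatin"),
      class = "statin", subtype = ""),
    data.table::data.table(
      drug_code = c("gemfibrozil", "fenofibrate", "niacin", "ezetimibe"),
      class = "ALP", subtype = ""),
    data.table::data.table(
      drug_code = c("lisinopril", "amlodipine", "hydrochlorothiazide",
                    "metoprolol"),
      class = "AHT", subtype = ""),
    data.table::data.table(drug_code = "aspirin", class = "ASA", subtype = ""),
    data.table::data.table(drug_code = "tenofovir", class = "NRTI",
                           subtype = "tenofovir"),
    data.table::data.table(drug_code = c("lamivudine", "emtricitabine"),
                           class = "NRTI", subtype = "lamivudine_emtricitabine"),
    data.table::data.table(drug_code = c("zidovudine", "abacavir",
                                         "stavudine", "didanosine"),
                           class = "NRTI", subtype = "other"),
    data.table::data.table(drug_code = c("efavirenz", "darunavir",
                                         "raltegravir", "dolutegravir"),
                           class = "anchor", subtype = "modern"),
    data.table::data.table(drug_code = c("lopinavir", "atazanavir"),
                           class = "anchor", subtype = "boosted_pi_other"),
    data.table::data.table(drug_code = c("indinavir", "nevirapine"),
                           class = "anchor", subtype = "unboosted_or_nvp_other"),
    data.table::data.table(drug_code = "ritonavir", class = "booster",
                           subtype = "")))
}
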