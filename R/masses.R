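# Monoisotopic masses and the shipped biotransformation / vocabulary tables.

# Most-abundant-isotope masses (Da), CODATA/IUPAC values.
.monoisotopic <- c(
  H = 1.00782503207,
  C = 12.0,
  N = 14.0030740048,
  O = 15.9949146196,
  P = 30.97376163,
  S = 31.97207100
)

#' Monoisotopic mass of a molecular formula
#'
#' Computes the monoisotopic (most-abundant-isotope) mass of a simple
#' CHNOPS formula such as `"C6H10O5"`.  Used to derive the shipped
#' biotransformation mass deltas from atomic masses rather than hard-coding
#' literature values.
#'
#' @param formula Character vector of molecular formulas (element symbols
#'   followed by optional counts, e.g. `"C11H10O4"`).
#' @return Numeric vector of masses in Da.
#' @examples
#' monoisotopic_mass("C6H10O5") # hexose condensation residue, ~162.0528
#' @export
monoisotopic_mass <- function(formula) {
  map_dbl(formula, function(f) {
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    parts <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
    if (!length(parts) || paste(parts, collapse = "") != f) {
      stop_parse(sprintf("cannot parse molecular formula '%s'", f))
    }
    total <- 0
    for (p in parts) {
      el <- sub("[0-9]*$", "", p)
      cnt <- sub("^[A-Za-z]+", "", p)
      cnt <- if (nzchar(cnt)) as.numeric(cnt) else 1
      if (!el %in% names(.monoisotopic)) {
        stop_parse(sprintf("unknown element '%s' in formula '%s'", el, f))
      }
      total <- total + .monoisotopic[[el]] * cnt
    }
    total
  })
}

#' Default biotransformation mass-difference table
#'
#' Common plant decoration reactions and the monoisotopic mass shift each
#' imposes on a metabolite (the mass of the group gained, after loss of
#' water where the reaction is a condensation).  Deltas are computed from
#' atomic masses at call time, not transcribed.
#'
#' @return A tibble with columns `name`, `formula` and `delta_da` (Da).
#' @seealso [massdiff_edges()]
#' @export
default_biotransformations <- function() {
  tab <- tibble(
    name = c("methylation", "hydroxylation", "acetylation", "malonylation",
             "rhamnosylation", "glycosylation", "sinapoylation"),
    formula = c("CH2", "O", "C2H2O", "C3H2O3",
                "C6H10O4", "C6H10O5", "C11H10O4")
  )
  tab$delta_da <- monoisotopic_mass(tab$formula)
  tab
}

#' Default enzyme-class map
#'
#' Maps protein-domain identifiers (as produced by a profile-HMM scan of the
#' proteome) to the enzyme-class vocabulary used throughout the package, and
#' flags which classes are scaffold-generating (classes that build a
#' metabolite backbone rather than decorate it).  Fully user-overridable;
#' this default covers the families most often implicated in plant
#' specialized metabolism.
#'
#' @return A tibble with columns `domain_id`, `class`, `scaffold` (logical).
#' @export
default_enzyme_class_map <- function() {
  tibble(
    domain_id = c("Dirigent", "2OG-FeII_Oxy", "Chal_sti_synt_N",
                  "UDPGT", "Transferase", "p450", "Terpene_synth_C",
                  "SQHop_cyclase_C", "Methyltransf_2", "Glyco_hydro_1"),
    class = c("dirigent", "dioxygenase", "chalcone_stilbene_synthase",
              "glycosyltransferase", "acyltransferase", "cytochrome_p450",
              "terpene_synthase", "oxidosqualene_cyclase",
              "methyltransferase", "beta_glucosidase"),
    scaffold = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE,
                 FALSE, FALSE)
  )
}

#' Default compound-class / enzyme-class compatibility map
#'
#' Which enzyme classes are considered pathway-compatible with a metabolite
#' compound class when classifying a BGC-mQTL link: lignans with dirigent
#' enzymes and dioxygenases, flavonoids with chalcone/stilbene synthases,
#' glycosyltransferases and acyltransferases, terpenes with terpene synthases
#' and oxidosqualene cyclases.  Long format; extend or replace freely.
#'
#' @return A tibble with columns `compound_class`, `enzyme_class`.
#' @export
default_compatibility_map <- function() {
  tibble(
    compound_class = c("lignan", "lignan",
                       "flavonoid", "flavonoid", "flavonoid",
                       "terpene", "terpene"),
    enzyme_class = c("dirigent", "dioxygenase",
                     "chalcone_stilbene_synthase", "glycosyltransferase",
                     "acyltransferase",
                     "terpene_synthase", "oxidosqualene_cyclase")
  )
}
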