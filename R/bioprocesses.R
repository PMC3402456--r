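#' Canonical cancer-related bioprocess class instances
#'
#' The six Gene Ontology processes conventionally used as the
#' cancer-promoting and cancer-resisting bioprocess classes:
#' positive regulation of cell proliferation (GO:0008284), negative
#' regulation of apoptosis (GO:0043066) and positive regulation of
#' angiogenesis (GO:0045766) promote cancer; negative regulation of
#' cell proliferation (GO:0008285), positive regulation of apoptosis
#' (GO:0043065) and negative regulation of angiogenesis (GO:0016525)
#' resist it.
#'
#' @return A tibble with columns `bioprocess` (atom), `class`
#'   (`"promoting_bp"`/`"resisting_bp"`) and `go_id`.
#' @examples
#' bp <- cancer_bioprocess_classes()
#' kb <- knowledge_base(
#'   promoting_bps = bp$bioprocess[bp$class == "promoting_bp"],
#'   resisting_bps = bp$bioprocess[bp$class == "resisting_bp"]
#' )
#' @export
cancer_bioprocess_classes <- function() {
  tibble(
    bioprocess = c("pos_reg_cell_proliferation", "neg_reg_apoptosis",
                   "pos_reg_angiogenesis",
                   "neg_reg_cell_proliferation", "pos_reg_apoptosis",
                   "neg_reg_angiogenesis"),
    class = rep(c("promoting_bp", "resisting_bp"), each = 3),
    go_id = c("GO:0008284", "GO:0043066", "GO:0045766",
              "GO:0008285", "GO:0043065", "GO:0016525")
  )
}
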