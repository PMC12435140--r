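#' Desikan-Killiany-Tourville cortical region registry
#'
#' The DKT atlas parcellates the cortex into 31 regions per hemisphere
#' (62 in total); region-wise cortical thickness tables are indexed by
#' these labels. Labels are returned as `"lh <region>"` / `"rh <region>"`.
#'
#' @param hemi `"both"` (default), `"lh"`, or `"rh"`.
#' @return Character vector of region labels (62 for `"both"`).
#' @export
#' @examples
#' length(dkt_labels())        # 62
#' length(dkt_labels("lh"))    # 31
dkt_labels <- function(hemi = c("both", "lh", "rh")) {
  hemi <- match.arg(hemi)
  base <- c(
    "caudal anterior cingulate", "caudal middle frontal", "cuneus",
    "entorhinal", "fusiform", "inferior parietal", "inferior temporal",
    "isthmus cingulate", "lateral occipital", "lateral orbitofrontal",
    "lingual", "medial orbitofrontal", "middle temporal",
    "parahippocampal", "paracentral", "pars opercularis",
    "pars orbitalis", "pars triangularis", "pericalcarine",
    "postcentral", "posterior cingulate", "precentral", "precuneus",
    "rostral anterior cingulate", "rostral middle frontal",
    "superior frontal", "superior parietal", "superior temporal",
    "supramarginal", "transverse temporal", "insula"
  )
  lh <- paste("lh", base)
  rh <- paste("rh", base)
  switch(hemi, both = c(lh, rh), lh = lh, rh = rh)
}
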