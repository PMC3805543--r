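#' Detect systolic peaks with a chosen method
#'
#' Thin dispatcher over the four detectors. All detectors return strictly
#' increasing 1-based sample indices within the record bounds.
#'
#' @param record A `ppg_record`.
#' @param method One of `"elgendi"` (event-related dual moving averages,
#'   the default), `"billauer"` (local extrema with an amplitude delta),
#'   `"li"` (first-derivative delineator), `"zong"` (slope sum).
#' @param params Optional parameter bundle for the chosen method; defaults
#'   to that method's parameter constructor.
#' @return A `peak_annotation`.
#' @examples
#' s <- synth_ppg(synth_preset("rest", seed = 42))
#' detect_peaks(s$record, "elgendi")
#' @export
detect_peaks <- function(record,
                         method = c("elgendi", "billauer", "li", "zong"),
                         params = NULL) {
  method <- match.arg(method)
  switch(method,
    elgendi  = detect_elgendi(record, params %||% elgendi_params()),
    billauer = detect_billauer(record, params %||% billauer_params()),
    li       = detect_li(record, params %||% li_params()),
    zong     = detect_zong(record, params %||% zong_params())
  )
}
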