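#' @importFrom data.table .N .SD := data.table
#' @importFrom stats setNames
#' @importFrom utils head tail
NULL

.datatable.aware <- TRUE
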