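# enable data.table [] semantics inside the package namespace
.datatable.aware <- TRUE

#' @importFrom data.table data.table fread fwrite as.data.table rbindlist
#' @importFrom stats runif rnorm
#' @importFrom utils head packageVersion
NULL
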