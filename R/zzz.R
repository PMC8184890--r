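#' @keywords internal
"_PACKAGE"

## let data.table's [ semantics work inside the package namespace
.datatable.aware <- TRUE

#' @importFrom data.table :=
#' @importFrom stats median qnorm pnorm rbinom runif rnorm rexp rlnorm
NULL

utils::globalVariables(c(".BY", "day", "start", "end", "tss"))
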