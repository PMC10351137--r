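#' @importFrom stats rbinom runif rlnorm rnbinom uniroot cor phyper sd var
#'   t.test setNames
#' @importFrom utils read.table write.table head adist
#' @keywords internal
"_PACKAGE"
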