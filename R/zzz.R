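#' @useDynLib nanodegosc
#' @importFrom stats setNames
#' @importFrom utils read.csv write.csv
#' @keywords internal
"_PACKAGE"
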