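#' @useDynLib SynaptoSeg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods is new validObject setValidity slot
#' @import stats
#' @importFrom utils read.csv write.csv packageVersion
"_PACKAGE"
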