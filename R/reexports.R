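# Re-exported generics so tidy()/glance() work without attaching broom or
# generics explicitly.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
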