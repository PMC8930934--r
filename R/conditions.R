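# Typed error conditions so callers (and cohort aggregation) can distinguish
# "structure absent" from "measure legitimately zero".

abort_menisq <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "menisq_error", "error"),
                      call = call))
}

is_menisq_error <- function(e, class) inherits(e, class)
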