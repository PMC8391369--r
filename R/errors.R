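# Condition constructors. Every package error signals a classed condition so
# callers (and the CLI) can map failure modes to exit codes without string
# matching.

rt_error <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "rt_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

rt_schema_error         <- function(msg) rt_error("rt_schema_error", msg)
rt_unknown_slot_error   <- function(msg) rt_error("rt_unknown_slot_error", msg)
rt_not_found_error      <- function(msg) rt_error("rt_not_found_error", msg)
rt_kb_syntax_error      <- function(msg) rt_error("rt_kb_syntax_error", msg)
rt_kb_slot_error        <- function(msg) rt_error("rt_kb_slot_error", msg)
rt_session_closed_error <- function(msg) rt_error("rt_session_closed_error", msg)
rt_empty_reference_error <- function(msg) rt_error("rt_empty_reference_error", msg)
rt_empty_input_error    <- function(msg) rt_error("rt_empty_input_error", msg)
rt_invalid_vote_error   <- function(msg) rt_error("rt_invalid_vote_error", msg)
rt_length_mismatch_error <- function(msg) rt_error("rt_length_mismatch_error", msg)
rt_constant_input_error <- function(msg) rt_error("rt_constant_input_error", msg)
rt_range_error          <- function(msg) rt_error("rt_range_error", msg)
rt_insufficient_kb_error <- function(msg) rt_error("rt_insufficient_kb_error", msg)
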