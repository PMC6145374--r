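# Classed error conditions so callers can branch on failure modes
# (degenerate pools must be sampled, infeasible labelings rejected).
bl_stop <- function(class, message, data = list()) {
  cond <- structure(
    class = c(class, "bl_error", "error", "condition"),
    c(list(message = message, call = sys.call(-1)), data)
  )
  stop(cond)
}

is_degenerate_signal <- function(e) inherits(e, "bl_degenerate_pool")
is_infeasible_signal <- function(e) inherits(e, "bl_infeasible_labeling")
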