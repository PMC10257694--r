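# Classed error conditions so callers can distinguish failure modes
# programmatically (e.g. tryCatch(..., diascore_too_few_records = ...)).

abort_diascore <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("diascore_", class), "diascore_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

stop_missing_column <- function(col) {
  abort_diascore("missing_column", sprintf("missing mandatory column '%s'", col))
}

stop_malformed_value <- function(col, row) {
  abort_diascore(
    "malformed_value",
    sprintf("non-finite value in subscore column '%s' at row %d", col, row)
  )
}
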