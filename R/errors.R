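# Classed conditions so callers (and the CLI) can map failures to exit codes.

mc_abort <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "molcollab_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

abort_unknown_molecule <- function(name) {
  mc_abort(sprintf("unknown molecule: '%s' matches no molecule name or alias", name),
           "mc_unknown_molecule", name = name)
}

abort_unknown_author <- function(key) {
  mc_abort(sprintf("unknown author: '%s'", key), "mc_unknown_author", name = key)
}

abort_unknown_publication <- function(id) {
  mc_abort(sprintf("unknown publication: '%s'", id), "mc_unknown_publication", name = id)
}

abort_parse <- function(path, line, why) {
  mc_abort(sprintf("parse error in '%s' at line %d: %s", path, line, why),
           "mc_parse_error", path = path, line = line)
}

abort_domain <- function(msg) mc_abort(msg, "mc_domain_error")

abort_insufficient <- function(what, need, have) {
  mc_abort(sprintf("insufficient %s: need %d, have %d", what, need, have),
           "mc_insufficient_data", what = what, need = need, have = have)
}
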