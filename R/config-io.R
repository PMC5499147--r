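#' Read and write model configurations
#'
#' Model parameter sets serialize to a flat JSON document keyed by parameter
#' name. Full double precision is retained so a write/read round trip
#' reproduces the model exactly.
#'
#' @param model An [autoimmune_model()] object.
#' @param path File path for the JSON configuration.
#' @return `write_model_config()` returns `path` invisibly;
#'   `read_model_config()` returns an [autoimmune_model()].
#' @export
write_model_config <- function(model, path) {
  stopifnot(inherits(model, "imm_model"))
  cfg <- c(
    list(p0 = model$p0, p1 = model$p1, p2 = model$p2, q1 = model$q1,
         T_total = model$T_total),
    model$psi[],
    model$scaling[paste0("r", 1:6)],
    list(A = model$scaling$A)
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- lapply(cfg, function(x) if (is.numeric(x)) as.numeric(x) else x)
  autoimmune_model(
    p0 = cfg$p0, p1 = cfg$p1, p2 = cfg$p2, q1 = cfg$q1,
    psi = jacobian_psi(cfg$H1i, cfg$H1j, cfg$H1k, cfg$H2j, cfg$H2k,
                       cfg$H3j, cfg$H3k),
    scaling = dose_scaling(cfg$r1, cfg$r2, cfg$r3, cfg$r4, cfg$r5, cfg$r6,
                           A = cfg$A),
    T_total = cfg$T_total
  )
}
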