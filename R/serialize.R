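#' Serialize a global test result
#'
#' `result_json()` returns a JSON string with the scalar fields of a
#' [compare_profiles()] result plus the eigenvalue spectrum;
#' `write_result_tsv()` writes the scalar fields as a one-row TSV.
#'
#' @param fit A `global_profile_test`.
#' @param path File path (TSV writer).
#' @return `result_json()` a JSON string; `write_result_tsv()` the path,
#'   invisibly.
#' @export
result_json <- function(fit) {
  stopifnot(inherits(fit, "global_profile_test"))
  jsonlite::toJSON(list(
    d = fit$d, V = fit$V, p_value = fit$p_value, alpha = fit$alpha,
    reject = fit$reject, ci_lower = fit$ci_lower, ci_upper = fit$ci_upper,
    sigma_hat = fit$sigma_hat, n = fit$n, m = fit$m, k = fit$k, s = fit$s,
    beta = fit$beta), auto_unbox = TRUE, digits = NA)
}

#' @rdname result_json
#' @export
write_result_tsv <- function(fit, path) {
  stopifnot(inherits(fit, "global_profile_test"))
  df <- data.frame(d = fit$d, V = fit$V, p_value = fit$p_value,
                   alpha = fit$alpha, reject = fit$reject,
                   ci_lower = fit$ci_lower, ci_upper = fit$ci_upper,
                   sigma_hat = fit$sigma_hat,
                   n = fit$n, m = fit$m, k = fit$k, s = fit$s)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
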