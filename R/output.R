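# Result serialization (JSON) and presentation-layer plots.

#' Serialize a fitted risk model to JSON
#'
#' Writes the posterior and future-risk tables as a nested JSON document:
#' `posterior.prob` maps each proband id to its genotype table (fields
#' `genes`, `estimate`, `lower`, `upper`) and `future.risk` maps each
#' proband id to a per-cancer table (fields `ByAge`, `estimate`, `lower`,
#' `upper`). A proband with no remaining cancers gets an explicit empty
#' object. [read_result()] round-trips the document.
#'
#' @param x A `mendel_risk` object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_result <- function(x, path) {
  stopifnot(inherits(x, "mendel_risk"))
  post <- list()
  for (pid in unique(x$posterior$proband)) {
    tab <- x$posterior[x$posterior$proband == pid, ]
    post[[as.character(pid)]] <- list(
      genes = tab$genotype, estimate = tab$estimate,
      lower = tab$lower, upper = tab$upper)
  }
  risk <- list()
  for (pid in unique(x$posterior$proband)) {
    per_cancer <- setNames(list(), character(0))
    tab <- x$future_risk[x$future_risk$proband == pid, ]
    for (cc in unique(tab$cancer)) {
      sub <- tab[tab$cancer == cc, ]
      per_cancer[[cc]] <- list(ByAge = sub$by_age, estimate = sub$estimate,
                               lower = sub$lower, upper = sub$upper)
    }
    risk[[as.character(pid)]] <- per_cancer
  }
  doc <- list(`posterior.prob` = post, `future.risk` = risk,
              genotypes = x$genotypes, cancers = x$cancers,
              gene_variants = x$gene_variants,
              max_mut = x$max_mut, iterations = x$iterations)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = FALSE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a serialized risk-model result
#'
#' @param path Path to a JSON file written by [write_result()].
#' @return A `mendel_risk` object carrying the posterior and future-risk
#'   tables (the check report is not serialized).
#' @export
read_result <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  post <- bind_rows(lapply(names(doc$`posterior.prob`), function(pid) {
    tab <- doc$`posterior.prob`[[pid]]
    tibble(proband = as.integer(pid), genotype = as.character(tab$genes),
           estimate = as.numeric(tab$estimate),
           lower = as.numeric(tab$lower), upper = as.numeric(tab$upper))
  }))
  risk_rows <- list()
  for (pid in names(doc$`future.risk`)) {
    per_cancer <- doc$`future.risk`[[pid]]
    for (cc in names(per_cancer)) {
      tab <- per_cancer[[cc]]
      risk_rows[[length(risk_rows) + 1L]] <- tibble(
        proband = as.integer(pid), cancer = cc,
        by_age = as.integer(tab$ByAge), estimate = as.numeric(tab$estimate),
        lower = as.numeric(tab$lower), upper = as.numeric(tab$upper))
    }
  }
  future <- if (length(risk_rows)) {
    bind_rows(risk_rows)
  } else {
    tibble(proband = integer(0), cancer = character(0), by_age = integer(0),
           estimate = numeric(0), lower = numeric(0), upper = numeric(0))
  }
  structure(
    list(posterior = post, future_risk = future, report = new_check_report(),
         cancers = as.character(doc$cancers),
         gene_variants = as.character(doc$gene_variants),
         genotypes = as.character(doc$genotypes),
         max_mut = as.integer(doc$max_mut),
         iterations = as.integer(doc$iterations),
         options = model_options()),
    class = "mendel_risk")
}

#' Plot posterior carrier probabilities
#'
#' Bar chart of the genotype posterior per proband, with imputation bounds
#' as error bars (they collapse onto the bars when nothing was imputed).
#'
#' @param x A `mendel_risk` object.
#' @param path Optional file path; when given the plot is also saved there.
#' @return A ggplot object.
#' @export
plot_posterior <- function(x, path = NULL) {
  stopifnot(inherits(x, "mendel_risk"))
  df <- x$posterior
  df$genotype <- factor(df$genotype, levels = x$genotypes)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$genotype, y = .data$estimate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                           width = 0.25) +
    ggplot2::facet_wrap(ggplot2::vars(.data$proband),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "posterior probability") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (!is.null(path)) ggplot2::ggsave(path, p, width = 8, height = 5)
  p
}

#' Plot future cancer risk curves
#'
#' Risk against age per proband and cancer, with the imputation range as a
#' ribbon (the ribbon collapses onto the line when nothing was imputed).
#'
#' @inheritParams plot_posterior
#' @return A ggplot object.
#' @export
plot_risk <- function(x, path = NULL) {
  stopifnot(inherits(x, "mendel_risk"))
  df <- x$future_risk
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$by_age, y = .data$estimate,
                                        colour = .data$cancer,
                                        fill = .data$cancer)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$proband),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "age", y = "cumulative future risk",
                  colour = "cancer", fill = "cancer") +
    ggplot2::theme_minimal()
  if (!is.null(path)) ggplot2::ggsave(path, p, width = 8, height = 5)
  p
}

#' Autoplot method for fitted risk models
#'
#' @param object A `mendel_risk` object.
#' @param type `"risk"` (default) or `"posterior"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mendel_risk <- function(object, type = c("risk", "posterior"), ...) {
  type <- match.arg(type)
  if (type == "risk" && nrow(object$future_risk)) {
    plot_risk(object)
  } else {
    plot_posterior(object)
  }
}
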