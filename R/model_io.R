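# Versioned single-file JSON text format for trained models, so a model
# trained once can be reused across scans and shipped between machines.

.MODEL_FORMAT <- "crmscout-model"
.MODEL_VERSION <- 1L

#' @keywords internal
.chain_to_list <- function(m) {
  list(type = class(m)[1L], order = m$order, logcond = m$logcond,
       pseudocount = m$pseudocount,
       count_threshold = m$count_threshold, conf_cutoff = m$conf_cutoff)
}

#' @keywords internal
.chain_from_list <- function(l) {
  structure(list(order = as.integer(l$order),
                 logcond = lapply(l$logcond, as.numeric),
                 pseudocount = l$pseudocount,
                 count_threshold = l$count_threshold,
                 conf_cutoff = l$conf_cutoff),
            class = l$type)
}

#' Write a trained model to a JSON text file
#'
#' Supports `crm_scorer` and `regulus_hmm` objects.
#'
#' @param model the model object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  if (inherits(model, "crm_scorer")) {
    body <- list(format = .MODEL_FORMAT, version = .MODEL_VERSION,
                 class = "crm_scorer", kind = model$kind, k = model$k,
                 scorer_id = model$scorer_id)
    if (model$kind == "pacrc") {
      p <- model$positive
      body$pac <- list(k = p$k, n = p$n, lambda = p$lambda, fval = p$fval,
                       canon = p$canon, rc_collapsed = p$rc_collapsed,
                       lambda_floor = p$lambda_floor)
    } else {
      body$positive <- .chain_to_list(model$positive)
      body$negative <- .chain_to_list(model$negative)
    }
  } else if (inherits(model, "regulus_hmm")) {
    body <- list(format = .MODEL_FORMAT, version = .MODEL_VERSION,
                 class = "regulus_hmm",
                 pwms = lapply(model$pwms, function(p) {
                   list(id = p$id, mat = p$mat, pseudocount = p$pseudocount)
                 }),
                 trans = model$trans, bg_trans = model$bg_trans,
                 bg_emission = model$bg_emission, phi = model$phi,
                 target_mean = model$target_mean,
                 densities = model$densities)
  } else {
    stop("unsupported model class: ", class(model)[1L], call. = FALSE)
  }
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' Read a trained model from a JSON text file
#' @param path path written by [write_model()].
#' @return the model object.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(l$format, .MODEL_FORMAT)) {
    stop("not a crmscout model file: ", path, call. = FALSE)
  }
  if (identical(l$class, "crm_scorer")) {
    if (l$kind == "pacrc") {
      pos <- structure(list(k = as.integer(l$pac$k), n = as.numeric(l$pac$n),
                            lambda = as.numeric(l$pac$lambda),
                            fval = as.numeric(l$pac$fval),
                            canon = as.numeric(l$pac$canon),
                            rc_collapsed = l$pac$rc_collapsed,
                            lambda_floor = l$pac$lambda_floor),
                       class = "pac_model")
      neg <- NULL
    } else {
      pos <- .chain_from_list(l$positive)
      neg <- .chain_from_list(l$negative)
    }
    structure(list(kind = l$kind, positive = pos, negative = neg,
                   k = as.integer(l$k), scorer_id = l$scorer_id),
              class = "crm_scorer")
  } else if (identical(l$class, "regulus_hmm")) {
    pwms <- lapply(l$pwms, function(p) {
      mat <- as.matrix(p$mat)
      rownames(mat) <- BASES
      structure(list(id = p$id, mat = mat, width = ncol(mat),
                     pseudocount = p$pseudocount), class = "pwm")
    })
    names(pwms) <- vapply(pwms, `[[`, "", "id")
    trans <- as.numeric(l$trans)
    names(trans) <- names(pwms)
    structure(list(pwms = pwms, trans = trans, bg_trans = l$bg_trans,
                   bg_emission = as.numeric(l$bg_emission), phi = l$phi,
                   target_mean = l$target_mean,
                   densities = as.numeric(l$densities)),
              class = "regulus_hmm")
  } else {
    stop("unknown model class in ", path, call. = FALSE)
  }
}
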