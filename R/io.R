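#' Write signal traces as tidy CSV
#'
#' Long format with columns `time_min`, `channel`, `value`, `condition_id`.
#' Numbers are written with 17 significant digits so that
#' [read_signal_csv()] inverts the writer bit-exactly.
#'
#' @param signals a [signal_trace()] or list of signal traces (e.g. the two
#'   channels of a coupled-network well).
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_signal_csv <- function(signals, path) {
  if (inherits(signals, "signal_trace")) signals <- list(signals)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("time_min,channel,value,condition_id", con)
  for (s in signals) {
    id <- if (is.na(s$condition_id)) "" else s$condition_id
    writeLines(sprintf("%.17g,%s,%.17g,%s", s$time, s$channel, s$value, id),
               con)
  }
  invisible(path)
}

#' Read signal traces from tidy CSV
#'
#' @param path CSV written by [write_signal_csv()] (or any file with the
#'   same columns).
#' @return named list of [signal_trace()]s, one per `(condition_id,
#'   channel)` pair, named `"<condition_id>.<channel>"` (or `"<channel>"`
#'   when the condition id is empty).
#' @export
read_signal_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c("numeric", "character",
                                             "numeric", "character"))
  keys <- paste(df$condition_id, df$channel, sep = ".")
  out <- lapply(split(seq_len(nrow(df)), keys), function(i) {
    signal_trace(time = df$time_min[i], value = df$value[i],
                 channel = df$channel[i][1],
                 condition_id = if (nzchar(df$condition_id[i][1]))
                   df$condition_id[i][1] else NA_character_)
  })
  names(out) <- sub("^\\.", "", names(out))
  out
}

#' Serialize lifetime results to JSON
#'
#' @param x a `lifetime_result`, `fatigue_report` or `fit_result`.
#' @param path optional output path.
#' @return the JSON string (invisibly when written).
#' @export
result_to_json <- function(x, path = NULL) {
  obj <- if (inherits(x, "lifetime_result")) {
    unclass(x)
  } else if (inherits(x, "fatigue_report")) {
    list(cycles = x$cycles, fatigued = x$fatigued, channel = x$channel)
  } else if (inherits(x, "fit_result")) {
    list(estimates = as.list(x$estimates), rss = x$rss,
         rss_channel = as.list(x$rss_channel), converged = x$converged,
         n_starts = x$n_starts, best_start = x$best_start,
         identifiable = as.list(x$identifiable),
         lower = as.list(x$lower), upper = as.list(x$upper), seed = x$seed)
  } else {
    stop("result_to_json: unsupported class")
  }
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                          dataframe = "columns", na = "null")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Batch lifetime summary CSV
#'
#' @param summaries data.frame with columns `condition_id`, `cycle`,
#'   `tau_min`, `delta_signal` (as produced by [cycle_lifetimes()] plus a
#'   condition label).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_lifetime_csv <- function(summaries, path) {
  utils::write.csv(summaries, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- SBML export --------------------------------------------------------

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

ml_ci <- function(x) sprintf("<ci> %s </ci>", x)
ml_cn <- function(x) sprintf("<cn> %.17g </cn>", x)
ml_apply <- function(op, ...) {
  sprintf("<apply><%s/>%s</apply>", op, paste(..., collapse = ""))
}

#' Export a reaction network to SBML Level 3
#'
#' Writes species (initial concentrations in uM), global parameters, and
#' reactions with full MathML kinetic laws (mass action and shared-
#' denominator competitive Michaelis-Menten), suitable for cross-checking
#' the model in an external SBML simulator. Toe-hold factors and enzyme-
#' unit conversions are folded into per-reaction `vmax` parameters.
#'
#' @param net a `reaction_network`.
#' @param params a [kinetic_params()] object.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_sbml <- function(net, params, path) {
  stopifnot(inherits(net, "reaction_network"))
  sp_xml <- vapply(net$species, function(s) {
    sprintf(paste0('      <species id="%s" compartment="well" ',
                   'initialConcentration="%.17g" hasOnlySubstanceUnits="false" ',
                   'boundaryCondition="false" constant="false"/>'),
            s, net$init[[s]])
  }, "")

  par_ids <- character(0)
  par_vals <- numeric(0)
  add_par <- function(id, val) {
    if (!id %in% par_ids) {
      par_ids <<- c(par_ids, id)
      par_vals <<- c(par_vals, val)
    }
    id
  }

  # shared denominators per competitive group
  groups <- list()
  for (r in net$reactions) {
    if (r$type == "competitive_mm") {
      add_par(r$Km, params[[r$Km]])
      groups[[r$group]] <- c(groups[[r$group]],
                             ml_apply("divide", ml_ci(r$substrate),
                                      ml_ci(r$Km)))
    }
  }
  denom_ml <- lapply(groups, function(terms) {
    ml_apply("plus", paste(c(ml_cn(1), terms), collapse = ""))
  })

  rx_xml <- vapply(seq_along(net$reactions), function(j) {
    r <- net$reactions[[j]]
    st <- r$stoich
    reactants <- names(st)[st < 0]
    products <- names(st)[st > 0]
    spref <- function(s, n) {
      sprintf(paste0('          <speciesReference species="%s" ',
                     'stoichiometry="%d" constant="true"/>'), s, abs(n))
    }
    math <- switch(r$type,
      mass_action = {
        add_par(r$k, params[[r$k]])
        ml_apply("times", paste(c(ml_ci(r$k),
                                  unlist(lapply(names(r$reactants), function(s) {
                                    rep(ml_ci(s), r$reactants[[s]])
                                  }))), collapse = ""))
      },
      first_order = {
        add_par(r$k, params[[r$k]])
        ml_apply("times", paste0(ml_ci(r$k), ml_ci(r$species)))
      },
      competitive_mm = {
        sat <- ml_apply("divide",
                        paste0(ml_apply("divide", ml_ci(r$substrate),
                                        ml_ci(r$Km)),
                               denom_ml[[r$group]]))
        if (r$group %in% c("exoIII", "t7")) {
          vid <- add_par(paste0("vmax_", r$name),
                         pool_vmax(r$group, r$L, net, params))
          ml_apply("times", paste0(ml_ci(vid), sat))
        } else {
          add_par(r$kcat, params[[r$kcat]])
          ml_apply("times", paste0(ml_ci(r$kcat), ml_ci(r$enzyme_species),
                                   sat))
        }
      })
    paste0(
      sprintf('      <reaction id="%s" reversible="false">\n', r$name),
      "        <listOfReactants>\n",
      paste(mapply(spref, reactants, st[reactants]), collapse = "\n"), "\n",
      "        </listOfReactants>\n",
      "        <listOfProducts>\n",
      paste(mapply(spref, products, st[products]), collapse = "\n"), "\n",
      "        </listOfProducts>\n",
      "        <kineticLaw>\n",
      '          <math xmlns="http://www.w3.org/1998/Math/MathML">\n',
      "            ", math, "\n",
      "          </math>\n",
      "        </kineticLaw>\n",
      "      </reaction>")
  }, "")

  par_xml <- mapply(function(id, val) {
    sprintf('      <parameter id="%s" value="%.17g" constant="true"/>',
            id, val)
  }, par_ids, par_vals)

  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" ',
    'level="3" version="2">\n',
    sprintf('  <model id="%s" timeUnits="minute">\n',
            xml_escape(net$circuit_id)),
    "    <listOfCompartments>\n",
    '      <compartment id="well" spatialDimensions="3" size="1" ',
    'constant="true"/>\n',
    "    </listOfCompartments>\n",
    "    <listOfSpecies>\n", paste(sp_xml, collapse = "\n"), "\n",
    "    </listOfSpecies>\n",
    "    <listOfParameters>\n", paste(par_xml, collapse = "\n"), "\n",
    "    </listOfParameters>\n",
    "    <listOfReactions>\n", paste(rx_xml, collapse = "\n"), "\n",
    "    </listOfReactions>\n",
    "  </model>\n",
    "</sbml>\n")
  writeLines(doc, path)
  invisible(path)
}
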