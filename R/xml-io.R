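# Corpus and external-assessment XML readers/writers.
#
# Corpus dialect (UTF-8):
#   <corpus>
#     <episode id="...">
#       <administration day="0"/> ...
#       <observation day="-6" value="0.333333"/> ...
#       <classification call="no_change" concordance="0.818182"
#                       agree_count="9" n_raters="11" intricacy="medium"
#                       standoff="false"/>
#       <vote rater="r01" category="no_change"/> ...   (optional)
#     </episode>
#   </corpus>
# External assessments (one category per curve id):
#   <assessment assessor="...">
#     <entry episode="..." category="no_change"/> ...
#   </assessment>
#
# Normalized values and concordance are serialized with 6 decimal places;
# output is deterministic (stable element order, fixed formatting), so
# writing the same corpus twice yields byte-identical files.

xml_attr_required <- function(node, attr, where) {
  v <- xml2::xml_attr(node, attr)
  if (is.na(v)) {
    abort_validation(where, ": missing required attribute '", attr, "'")
  }
  v
}

#' Write a corpus to an XML file
#'
#' Serializes a [corpus()] in the package's documented XML dialect: per
#' episode the relative administration days, the normalized observations
#' (6 decimal places), the classification, and (if present) the raw rater
#' votes. Output is deterministic: writing the same corpus twice produces
#' byte-identical files.
#'
#' @param x A [corpus()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(x, path) {
  stopifnot(inherits(x, "corpus"))
  doc <- xml2::xml_new_root("corpus")
  cls <- x$classifications
  for (i in seq_along(x$episodes)) {
    ep <- x$episodes[[i]]
    attrs <- c(id = ep$episode_id)
    if (!is.na(ep$truth_label)) {
      attrs <- c(attrs, truth = tolower(as.character(ep$truth_label)))
    }
    if (!is.na(ep$parameter_tag)) {
      attrs <- c(attrs, parameter = ep$parameter_tag)
    }
    node <- xml2::xml_add_child(doc, "episode")
    xml2::xml_set_attrs(node, attrs)
    for (d in ep$administration_days) {
      xml2::xml_add_child(node, "administration", day = as.character(d))
    }
    for (j in seq_len(nrow(ep$points))) {
      xml2::xml_add_child(node, "observation",
                          day = as.character(ep$points$relative_day[j]),
                          value = fmt_num(ep$points$value[j]))
    }
    k <- which(cls$episode_id == ep$episode_id)
    xml2::xml_add_child(node, "classification",
                        call = cls$call[k],
                        concordance = fmt_num(cls$concordance[k]),
                        agree_count = as.character(cls$agree_count[k]),
                        n_raters = as.character(cls$n_raters[k]),
                        intricacy = cls$intricacy[k],
                        standoff = tolower(as.character(cls$standoff[k])))
    if (!is.null(x$votes)) {
      v <- x$votes[x$votes$episode_id == ep$episode_id, , drop = FALSE]
      v <- v[order(v$rater_id), , drop = FALSE]
      for (j in seq_len(nrow(v))) {
        xml2::xml_add_child(node, "vote",
                            rater = v$rater_id[j], category = v$category[j])
      }
    }
  }
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) abort_io("cannot write to ", path, ": ",
                                               conditionMessage(e)))
  on.exit(close(con))
  xml2::write_xml(doc, con)
  invisible(path)
}

#' Read a corpus from an XML file
#'
#' Parses a corpus file written by [write_corpus()] (or any file in the same
#' dialect), reconstructs the episodes and classifications, and validates
#' every episode against the structural rules (see [validate_episode()]).
#' Invalid episodes abort with a diagnostic naming the episode and the
#' violated rule. Classification concordance is recomputed exactly from the
#' integer `agree_count / n_raters`; the serialized decimal value must agree
#' within 1e-6.
#'
#' @param path Path to a corpus XML file.
#' @param validate Validate episode structure (default `TRUE`).
#' @param max_internal_gap_days,min_obs_per_phase,flank_window_days
#'   Structural rule parameters passed to [validate_episode()].
#' @return A [corpus()].
#' @export
read_corpus <- function(path, validate = TRUE, max_internal_gap_days = 1L,
                        min_obs_per_phase = 5L, flank_window_days = 7L) {
  if (!file.exists(path)) abort_io("no such file: ", path)
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "corpus") {
    abort_validation(path, ": root element must be <corpus>, got <",
                     xml2::xml_name(doc), ">")
  }
  ep_nodes <- xml2::xml_find_all(doc, "./episode")
  episodes <- vector("list", length(ep_nodes))
  cls_rows <- vector("list", length(ep_nodes))
  vote_rows <- list()
  for (i in seq_along(ep_nodes)) {
    node <- ep_nodes[[i]]
    id <- xml_attr_required(node, "id", "episode")
    where <- paste0("episode ", id)
    adm <- xml2::xml_find_all(node, "./administration")
    obs <- xml2::xml_find_all(node, "./observation")
    truth <- xml2::xml_attr(node, "truth")
    param <- xml2::xml_attr(node, "parameter")
    ep <- episode(
      episode_id = id,
      administration_days = as.integer(xml2::xml_attr(adm, "day")),
      points = data.frame(
        relative_day = as.integer(xml2::xml_attr(obs, "day")),
        value = as.numeric(xml2::xml_attr(obs, "value"))),
      truth_label = if (is.na(truth)) NA else as.logical(toupper(truth)),
      parameter_tag = param)
    if (validate) {
      bad <- validate_episode(ep, max_internal_gap_days = max_internal_gap_days,
                              min_obs_per_phase = min_obs_per_phase,
                              flank_window_days = flank_window_days)
      if (length(bad) > 0) {
        abort_validation(where, ": ", paste(bad, collapse = "; "))
      }
    }
    episodes[[i]] <- ep
    cn <- xml2::xml_find_all(node, "./classification")
    if (length(cn) != 1) {
      abort_validation(where, ": expected exactly one <classification>, got ",
                       length(cn))
    }
    cn <- cn[[1]]
    agree <- as.integer(xml_attr_required(cn, "agree_count", where))
    n_rat <- as.integer(xml_attr_required(cn, "n_raters", where))
    conc_file <- as.numeric(xml_attr_required(cn, "concordance", where))
    if (abs(conc_file - agree / n_rat) > 1e-6) {
      abort_validation(where, ": serialized concordance ", conc_file,
                       " does not match agree_count/n_raters = ", agree, "/", n_rat)
    }
    cls_rows[[i]] <- data.frame(
      episode_id = id,
      call = check_category(xml_attr_required(cn, "call", where), where),
      concordance = agree / n_rat,
      agree_count = agree,
      n_raters = n_rat,
      intricacy = xml_attr_required(cn, "intricacy", where),
      standoff = as.logical(toupper(xml_attr_required(cn, "standoff", where))),
      stringsAsFactors = FALSE)
    vn <- xml2::xml_find_all(node, "./vote")
    if (length(vn) > 0) {
      vote_rows[[length(vote_rows) + 1L]] <- data.frame(
        episode_id = id,
        rater_id = xml2::xml_attr(vn, "rater"),
        category = check_category(xml2::xml_attr(vn, "category"), where),
        stringsAsFactors = FALSE)
    }
  }
  cls <- if (length(cls_rows) > 0) {
    do.call(rbind, c(cls_rows, list(make.row.names = FALSE)))
  } else {
    data.frame(episode_id = character(0), call = character(0),
               concordance = numeric(0), agree_count = integer(0),
               n_raters = integer(0), intricacy = character(0),
               standoff = logical(0), stringsAsFactors = FALSE)
  }
  corpus(episodes, cls,
         votes = if (length(vote_rows) > 0) {
           do.call(rbind, c(vote_rows, list(make.row.names = FALSE)))
         } else NULL)
}

#' Write an external assessment set to an XML file
#'
#' Counterpart of [read_external_assessment()]; one `<entry>` per episode
#' with its assigned category. Deterministic output (entries sorted by
#' episode id).
#'
#' @param x An [assessment_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_external_assessment <- function(x, path) {
  stopifnot(inherits(x, "assessment_set"))
  doc <- xml2::xml_new_root("assessment", assessor = x$assessor_id)
  for (i in seq_len(nrow(x$entries))) {
    xml2::xml_add_child(doc, "entry",
                        episode = x$entries$episode_id[i],
                        category = x$entries$category[i])
  }
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) abort_io("cannot write to ", path, ": ",
                                               conditionMessage(e)))
  on.exit(close(con))
  xml2::write_xml(doc, con)
  invisible(path)
}

#' Read an external assessment set from an XML file
#'
#' Reads the simple import structure used to compare any external assessment
#' (human session or algorithm output) against a ground-truth corpus: one
#' entry per curve id with exactly one of the three nominal categories.
#' Duplicate episode ids or unknown category strings abort with a diagnostic
#' naming the offending entry.
#'
#' @param path Path to an assessment XML file.
#' @return An [assessment_set()].
#' @export
read_external_assessment <- function(path) {
  if (!file.exists(path)) abort_io("no such file: ", path)
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "assessment") {
    abort_validation(path, ": root element must be <assessment>, got <",
                     xml2::xml_name(doc), ">")
  }
  assessor <- xml2::xml_attr(doc, "assessor")
  if (is.na(assessor)) assessor <- "external"
  entries <- xml2::xml_find_all(doc, "./entry")
  ids <- xml2::xml_attr(entries, "episode")
  if (anyNA(ids)) abort_validation(path, ": <entry> without an episode id")
  cats <- xml2::xml_attr(entries, "category")
  bad <- which(!(cats %in% assessment_categories()))
  if (length(bad) > 0) {
    abort_validation(path, ": entry for episode ", ids[bad[1]],
                     " has unknown category '", cats[bad[1]], "'")
  }
  assessment_set(assessor, ids, cats)
}
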