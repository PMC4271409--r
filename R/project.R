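# -- file-backed project store ------------------------------------------------
#
# A project pools exactly two named tree collections plus members, privacy
# status, a todo list, an append-only timeline, named backups, import limits
# and a single-writer control token. All mutating operations are pure: they
# take and return project values; persistence is explicit via save_project()
# / load_project().

#' Project limits
#'
#' @param max_trees_per_project maximum number of trees across both
#'   collections (default 10000)
#' @param max_taxa_per_project maximum number of distinct taxa across the
#'   project (default 5000)
#' @param max_trees_per_import maximum number of trees in a single import
#'   (default 1000)
#' @return a `project_limits` record
#' @export
project_limits <- function(max_trees_per_project = 10000L,
                           max_taxa_per_project = 5000L,
                           max_trees_per_import = 1000L) {
  stopifnot(max_trees_per_project >= 1, max_taxa_per_project >= 1,
            max_trees_per_import >= 1)
  structure(list(max_trees_per_project = as.integer(max_trees_per_project),
                 max_taxa_per_project = as.integer(max_taxa_per_project),
                 max_trees_per_import = as.integer(max_trees_per_import)),
            class = "project_limits")
}

# Single-writer control token state. Members and the administrator id are
# carried so the state is self-contained for authority checks.
new_control_state <- function(members, admin) {
  structure(list(members = members, admin = admin, holder = NA_character_,
                 pending = character(0),
                 sync = setNames(rep(TRUE, length(members)), members)),
            class = "control_state")
}

#' Create a new project
#'
#' Projects start private, with two empty collections ("Collection 1" and
#' "Collection 2"), the administrator as sole member, and a vacant control
#' token.
#'
#' @param name project name (non-empty; names are not unique keys — the
#'   opaque `id` field is)
#' @param admin member id of the administrator
#' @return a `phyloproject`
#' @export
create_project <- function(name, admin) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name))
    stop("project name must be a non-empty string", call. = FALSE)
  stopifnot(is.character(admin), length(admin) == 1, nzchar(admin))
  p <- structure(list(
    id = sprintf("prj-%s-%04x", format(Sys.time(), "%Y%m%d%H%M%S"),
                 as.integer(runif(1, 0, 65535))),
    name = name,
    admin = admin,
    members = data.frame(id = admin, role = "administrator",
                         stringsAsFactors = FALSE),
    status = "private",
    collections = list(tree_collection("Collection 1"),
                       tree_collection("Collection 2")),
    todo = character(0),
    timeline = data.frame(seq = integer(0), timestamp = character(0),
                          actor = character(0), kind = character(0),
                          summary = character(0), stringsAsFactors = FALSE),
    backups = list(),
    limits = project_limits(),
    control = new_control_state(admin, admin)),
    class = "phyloproject")
  p
}

#' @export
print.phyloproject <- function(x, ...) {
  nt <- sum(vapply(x$collections, length, integer(1)))
  cat("<phyloproject> '", x$name, "' (", x$status, "), ",
      nrow(x$members), " member(s), ", nt, " tree(s)\n", sep = "")
  cat("collections:",
      paste(vapply(x$collections, function(cl)
        sprintf("'%s' (%d)", cl$name, length(cl)), character(1)),
        collapse = ", "), "\n")
  holder <- x$control$holder
  cat("control holder:", if (is.na(holder)) "<vacant>" else holder, "\n")
  invisible(x)
}

timeline_event <- function(project, actor, kind, summary) {
  stopifnot(kind %in% c("import", "edit", "backup", "restore",
                        "control_change", "task_done"))
  s <- nrow(project$timeline) + 1L
  project$timeline <- rbind(project$timeline, data.frame(
    seq = s, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    actor = actor, kind = kind, summary = summary, stringsAsFactors = FALSE))
  project
}

is_member <- function(project, id) id %in% project$members$id

#' Invite a member into a project
#'
#' @param project a `phyloproject`
#' @param member new member id
#' @param actor acting member id; only the administrator can invite
#' @return the updated project
#' @export
add_member <- function(project, member, actor) {
  if (actor != project$admin)
    stop("only the administrator can invite members", call. = FALSE)
  if (is_member(project, member)) return(project)
  project$members <- rbind(project$members,
                           data.frame(id = member, role = "member",
                                      stringsAsFactors = FALSE))
  project$control$members <- project$members$id
  project$control$sync[member] <- TRUE
  project
}

#' Set the privacy status of a project
#' @param project a `phyloproject`
#' @param status `"private"` or `"public"`
#' @param actor acting member id; administrator only
#' @return the updated project
#' @export
set_status <- function(project, status, actor) {
  status <- match.arg(status, c("private", "public"))
  if (actor != project$admin)
    stop("only the administrator can change the project status", call. = FALSE)
  project$status <- status
  project
}

#' Attach or detach a member's synchronized view
#'
#' A detached member keeps read access but any mutating call is rejected
#' until they re-attach.
#'
#' @param project a `phyloproject`
#' @param member member id
#' @param attached logical
#' @return the updated project
#' @export
set_sync <- function(project, member, attached) {
  if (!is_member(project, member)) stop("not a member: ", member, call. = FALSE)
  project$control$sync[member] <- isTRUE(attached)
  project
}

collection_index <- function(project, collection) {
  nms <- vapply(project$collections, `[[`, character(1), "name")
  i <- match(collection, nms)
  if (is.na(i)) stop("no such collection: ", collection, call. = FALSE)
  i
}

#' Rename one of the two project collections
#' @param project a `phyloproject`
#' @param collection current collection name
#' @param new_name new collection name
#' @return the updated project
#' @export
rename_collection <- function(project, collection, new_name) {
  i <- collection_index(project, collection)
  stopifnot(is.character(new_name), nzchar(new_name))
  project$collections[[i]]$name <- new_name
  project
}

project_taxa <- function(project) {
  unique(unlist(lapply(project$collections, function(cl)
    lapply(cl$trees, tree_leaves)), use.names = FALSE))
}

# Authority for tree/collection mutation: the control holder, or the sole
# member of a single-member project; detached members are always rejected.
check_write_authority <- function(project, actor) {
  if (!is_member(project, actor))
    stop("control required: ", actor, " is not a member", call. = FALSE)
  if (!isTRUE(project$control$sync[[actor]]))
    stop("control required: ", actor, " is detached (synchronize first)",
         call. = FALSE)
  holder <- project$control$holder
  sole <- nrow(project$members) == 1L
  if (!sole && (is.na(holder) || holder != actor))
    stop("control required: ", actor, " does not hold the control token",
         call. = FALSE)
  invisible(TRUE)
}

#' Import trees into a project collection
#'
#' Trees are appended in order, their names deduplicated with a numeric
#' suffix. All limits are checked before any mutation: an import that would
#' exceed the per-import tree limit, the project tree limit or the project
#' taxon limit is rejected atomically and the project is returned unchanged
#' (an error is raised). The actor must hold the control token (or be the
#' project's only member).
#'
#' @param project a `phyloproject`
#' @param collection target collection name
#' @param trees list of `phytree`, optionally named
#' @param actor acting member id
#' @return the updated project
#' @export
import_trees <- function(project, collection, trees, actor) {
  check_write_authority(project, actor)
  i <- collection_index(project, collection)
  if (inherits(trees, "phytree")) trees <- list(trees)
  lim <- project$limits
  if (length(trees) > lim$max_trees_per_import)
    stop("import limit exceeded: ", length(trees), " trees > ",
         lim$max_trees_per_import, " per import", call. = FALSE)
  n_now <- sum(vapply(project$collections, length, integer(1)))
  if (n_now + length(trees) > lim$max_trees_per_project)
    stop("project limit exceeded: ", n_now + length(trees), " trees > ",
         lim$max_trees_per_project, " per project", call. = FALSE)
  new_taxa <- unique(c(project_taxa(project),
                       unlist(lapply(trees, tree_leaves), use.names = FALSE)))
  if (length(new_taxa) > lim$max_taxa_per_project)
    stop("project limit exceeded: ", length(new_taxa), " distinct taxa > ",
         lim$max_taxa_per_project, " per project", call. = FALSE)
  nm <- names(trees)
  if (is.null(nm)) nm <- rep("", length(trees))
  nm[!nzchar(nm)] <- paste0("tree_", seq_len(sum(!nzchar(nm))))
  taken <- names(project$collections[[i]]$trees)
  for (j in seq_along(nm)) {
    base <- nm[j]
    cand <- base
    k <- 1L
    while (cand %in% taken || cand %in% nm[seq_len(j - 1L)]) {
      k <- k + 1L
      cand <- paste0(base, "_", k)
    }
    nm[j] <- cand
  }
  names(trees) <- nm
  project$collections[[i]]$trees <- c(project$collections[[i]]$trees, trees)
  timeline_event(project, actor, "import",
                 sprintf("imported %d tree(s) into '%s'", length(trees),
                         collection))
}

# -- control token ------------------------------------------------------------

#' Request the control token
#'
#' If the token is vacant the requester becomes holder immediately; otherwise
#' the requester joins the pending queue (idempotently).
#'
#' @param state a `control_state` (e.g. `project$control`)
#' @param requester member id
#' @return the updated `control_state`
#' @export
request_control <- function(state, requester) {
  stopifnot(inherits(state, "control_state"))
  if (!requester %in% state$members)
    stop("not a member: ", requester, call. = FALSE)
  if (identical(state$holder, requester)) return(state)
  if (is.na(state$holder)) {
    state$holder <- requester
    return(state)
  }
  if (!requester %in% state$pending)
    state$pending <- c(state$pending, requester)
  state
}

#' Accept or decline a pending control request
#'
#' Only the current holder or the administrator may decide. On acceptance
#' the requester becomes the holder; on decline the holder is unchanged. In
#' both cases the requester leaves the pending queue.
#'
#' @param state a `control_state`
#' @param decider member id of the current holder or the administrator
#' @param requester pending member id
#' @param accept logical
#' @return the updated `control_state`
#' @export
resolve_request <- function(state, decider, requester, accept) {
  stopifnot(inherits(state, "control_state"))
  if (!(identical(state$holder, decider) || identical(state$admin, decider)))
    stop("only the control holder or the administrator can decide requests",
         call. = FALSE)
  if (!requester %in% state$pending)
    stop("no pending request from: ", requester, call. = FALSE)
  state$pending <- setdiff(state$pending, requester)
  if (isTRUE(accept)) state$holder <- requester
  state
}

#' Take the control token (administrator only)
#'
#' The administrator becomes holder regardless of the previous holder; the
#' pending queue is unchanged.
#'
#' @param state a `control_state`
#' @param actor member id; must be the administrator
#' @return the updated `control_state`
#' @export
take_control <- function(state, actor) {
  stopifnot(inherits(state, "control_state"))
  if (!identical(state$admin, actor))
    stop("only the administrator can take the control", call. = FALSE)
  state$holder <- actor
  state$pending <- setdiff(state$pending, actor)
  state
}

#' Project-level control operations with timeline recording
#'
#' Convenience wrappers applying [request_control()], [resolve_request()] or
#' [take_control()] to `project$control` and appending a `control_change`
#' timeline event whenever the holder changes.
#'
#' @param project a `phyloproject`
#' @param op one of `"request"`, `"accept"`, `"decline"`, `"take"`
#' @param actor acting member id (requester for `"request"`, decider for
#'   `"accept"`/`"decline"`, administrator for `"take"`)
#' @param requester pending requester id (for `"accept"`/`"decline"`)
#' @return the updated project
#' @export
project_control <- function(project, op = c("request", "accept", "decline",
                                            "take"),
                            actor, requester = NULL) {
  op <- match.arg(op)
  before <- project$control$holder
  project$control <- switch(op,
    request = request_control(project$control, actor),
    accept = resolve_request(project$control, actor, requester, TRUE),
    decline = resolve_request(project$control, actor, requester, FALSE),
    take = take_control(project$control, actor))
  after <- project$control$holder
  if (!identical(before, after))
    project <- timeline_event(project, actor, "control_change",
                              sprintf("control passed to %s", after))
  project
}

#' Access control decision
#'
#' Reads are allowed for members always and for guests only on public
#' projects. Writes are allowed for members only, and tree/collection
#' mutations additionally require the control token (checked by the mutating
#' operations themselves); guests can never write.
#'
#' @param project a `phyloproject`
#' @param actor member id or any non-member (guest) id
#' @param action `"read"` or `"write"`
#' @return `"allow"` or `"deny"` (never raises)
#' @export
check_access <- function(project, actor, action = c("read", "write")) {
  action <- match.arg(action)
  member <- is_member(project, actor)
  if (action == "read") {
    if (member || project$status == "public") return("allow")
    return("deny")
  }
  if (!member) return("deny")
  "allow"
}

# -- backups ------------------------------------------------------------------

#' Snapshot the project collections under a label
#' @param project a `phyloproject`
#' @param label backup label
#' @param actor acting member id (for the timeline; default administrator)
#' @return the updated project
#' @export
backup <- function(project, label, actor = project$admin) {
  stopifnot(is.character(label), nzchar(label))
  project$backups[[label]] <- project$collections
  timeline_event(project, actor, "backup", sprintf("backup '%s'", label))
}

#' Restore the project collections from a backup
#'
#' Replaces the current collections with the snapshot; the backups
#' themselves are never deleted by a restore.
#'
#' @param project a `phyloproject`
#' @param label existing backup label
#' @param actor acting member id (for the timeline; default administrator)
#' @return the updated project
#' @export
restore <- function(project, label, actor = project$admin) {
  if (!label %in% names(project$backups))
    stop("unknown backup label: ", label, call. = FALSE)
  project$collections <- project$backups[[label]]
  timeline_event(project, actor, "restore", sprintf("restored '%s'", label))
}

#' Append a todo item
#' @param project a `phyloproject`
#' @param item todo text
#' @return the updated project
#' @export
add_todo <- function(project, item) {
  project$todo <- c(project$todo, item)
  project
}

#' Mark a todo item done, registering it on the timeline
#' @param project a `phyloproject`
#' @param item existing todo text
#' @param actor acting member id
#' @return the updated project
#' @export
complete_task <- function(project, item, actor) {
  if (!item %in% project$todo) stop("no such task: ", item, call. = FALSE)
  project$todo <- setdiff(project$todo, item)
  timeline_event(project, actor, "task_done", item)
}

# -- persistence --------------------------------------------------------------

#' Save a project to a directory
#'
#' Layout: `metadata.json` (members, status, timeline, control, limits,
#' todo), one Newick file plus one annotation CSV per collection, and one
#' timestamped subdirectory per backup with the same per-collection files.
#'
#' @param project a `phyloproject`
#' @param dir target directory (created if needed)
#' @return `dir`, invisibly
#' @export
save_project <- function(project, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  save_collections <- function(colls, where) {
    dir.create(where, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_along(colls)) {
      cl <- colls[[k]]
      base <- file.path(where, sprintf("collection%d", k))
      write_newick_file(unname(cl$trees), paste0(base, ".nwk"))
      ann <- do.call(rbind, c(lapply(cl$trees, annotations_df),
                              make.row.names = FALSE))
      if (is.null(ann))
        ann <- data.frame(taxon = character(0), key = character(0),
                          value = character(0))
      write.csv(ann, paste0(base, "_annotations.csv"), row.names = FALSE)
      writeLines(c(cl$name, names(cl$trees)), paste0(base, "_names.txt"))
    }
  }
  save_collections(project$collections, file.path(dir, "collections"))
  for (lab in names(project$backups))
    save_collections(project$backups[[lab]],
                     file.path(dir, "backups", utils::URLencode(lab, TRUE)))
  meta <- list(id = project$id, name = project$name, admin = project$admin,
               members = project$members, status = project$status,
               todo = project$todo, timeline = project$timeline,
               limits = unclass(project$limits),
               backup_labels = names(project$backups),
               control = list(holder = project$control$holder,
                              pending = project$control$pending,
                              sync = as.list(project$control$sync)))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, na = "null", digits = NA)
  invisible(dir)
}

#' Load a project from a directory written by [save_project()]
#' @param dir project directory
#' @return a `phyloproject`
#' @export
load_project <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  load_collections <- function(where) {
    colls <- list()
    for (k in 1:2) {
      base <- file.path(where, sprintf("collection%d", k))
      info <- readLines(paste0(base, "_names.txt"), warn = FALSE)
      cname <- info[[1]]
      tnames <- info[-1]
      trees <- if (file.exists(paste0(base, ".nwk")))
        read_newick(paste0(base, ".nwk")) else list()
      ann_path <- paste0(base, "_annotations.csv")
      if (file.exists(ann_path) && length(trees)) {
        trees <- lapply(trees, read_annotations, path = ann_path)
      }
      names(trees) <- tnames[seq_along(trees)]
      colls[[k]] <- tree_collection(cname, trees)
    }
    colls
  }
  p <- create_project(meta$name, meta$admin)
  p$id <- meta$id
  p$members <- as.data.frame(meta$members, stringsAsFactors = FALSE)
  p$status <- meta$status
  p$todo <- as.character(meta$todo %||% character(0))
  p$timeline <- if (length(meta$timeline))
    as.data.frame(meta$timeline, stringsAsFactors = FALSE)
  else p$timeline
  p$limits <- do.call(project_limits, as.list(meta$limits))
  p$collections <- load_collections(file.path(dir, "collections"))
  p$backups <- list()
  for (lab in meta$backup_labels %||% character(0))
    p$backups[[lab]] <- load_collections(
      file.path(dir, "backups", utils::URLencode(lab, TRUE)))
  ctl <- new_control_state(p$members$id, p$admin)
  h <- meta$control$holder
  ctl$holder <- if (is.null(h) || is.na(h)) NA_character_ else h
  ctl$pending <- as.character(meta$control$pending %||% character(0))
  if (length(meta$control$sync))
    ctl$sync[names(meta$control$sync)] <- unlist(meta$control$sync)
  p$control <- ctl
  p
}
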