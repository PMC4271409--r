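test_that("create_project starts private with two empty collections", {
  p <- create_project("HGT study", "u1")
  expect_equal(p$status, "private")
  expect_equal(p$members$id, "u1")
  expect_equal(vapply(p$collections, `[[`, character(1), "name"),
               c("Collection 1", "Collection 2"))
  expect_equal(sum(vapply(p$collections, length, integer(1))), 0)
  expect_true(is.na(p$control$holder))
  expect_error(create_project("", "u1"), "non-empty")
  # names are not unique keys; ids are
  q <- create_project("HGT study", "u2")
  expect_false(identical(p$id, q$id))
})

test_that("import_trees appends, deduplicates names, logs the timeline", {
  p <- create_project("prj", "u1")
  trees <- random_trees(5, 3, seed = 2)
  p <- import_trees(p, "Collection 1", trees, "u1")
  expect_length(p$collections[[1]]$trees, 3)
  expect_equal(nrow(p$timeline), 1)
  expect_equal(p$timeline$kind, "import")
  # same default names: deduplicated by numeric suffix
  p <- import_trees(p, "Collection 1", trees, "u1")
  expect_length(p$collections[[1]]$trees, 6)
  expect_false(anyDuplicated(names(p$collections[[1]]$trees)) > 0)
  expect_error(import_trees(p, "nope", trees, "u1"), "no such collection")
})

test_that("limits are enforced atomically before mutation", {
  p <- create_project("prj", "u1")
  p$limits <- project_limits(max_trees_per_project = 10,
                             max_taxa_per_project = 12,
                             max_trees_per_import = 4)
  t <- parse_newick("((t01,t02),t03);")
  expect_error(import_trees(p, "Collection 1", rep(list(t), 5), "u1"),
               "import limit exceeded")
  expect_length(p$collections[[1]]$trees, 0)

  p2 <- import_trees(p, "Collection 1", rep(list(t), 4), "u1")
  p2 <- import_trees(p2, "Collection 1", rep(list(t), 4), "u1")
  p2 <- import_trees(p2, "Collection 2", rep(list(t), 2), "u1")
  expect_error(import_trees(p2, "Collection 2", list(t), "u1"),
               "project limit exceeded")
  expect_equal(sum(vapply(p2$collections, length, integer(1))), 10)

  # taxon cap, counted across the whole project
  p3 <- create_project("prj", "u1")
  p3$limits <- project_limits(max_taxa_per_project = 6)
  p3 <- import_trees(p3, "Collection 1", random_trees(6, 1, seed = 1), "u1")
  big <- rename_taxa(random_trees(4, 1, seed = 2)[[1]],
                     setNames(paste0("x", 1:4), sprintf("t%02d", 1:4)))
  expect_error(import_trees(p3, "Collection 2", list(big), "u1"),
               "project limit exceeded")
  expect_length(p3$collections[[2]]$trees, 0)
})

test_that("default limits match the platform caps", {
  lim <- project_limits()
  expect_equal(lim$max_trees_per_project, 10000L)
  expect_equal(lim$max_taxa_per_project, 5000L)
  expect_equal(lim$max_trees_per_import, 1000L)
})

test_that("control token: request, resolve, take", {
  p <- create_project("prj", "u1")
  p <- add_member(p, "u2", "u1")
  p <- add_member(p, "u3", "u1")
  st <- p$control
  # vacant token: immediate grant
  st <- request_control(st, "u2")
  expect_equal(st$holder, "u2")
  # busy token: queue, idempotently
  st <- request_control(st, "u3")
  st <- request_control(st, "u3")
  expect_equal(st$pending, "u3")
  # decline by the admin (non-holder) leaves the holder in place
  st2 <- resolve_request(st, "u1", "u3", accept = FALSE)
  expect_equal(st2$holder, "u2")
  expect_length(st2$pending, 0)
  # accept by the holder transfers
  st3 <- resolve_request(st, "u2", "u3", accept = TRUE)
  expect_equal(st3$holder, "u3")
  # ordinary members cannot decide
  st <- request_control(st3, "u2")
  expect_error(resolve_request(st, "u2", "u2", TRUE), "holder or the admin")
  # admin takes over at any moment; idempotent
  st4 <- take_control(st, "u1")
  expect_equal(st4$holder, "u1")
  expect_equal(take_control(st4, "u1")$holder, "u1")
  expect_error(take_control(st4, "u3"), "administrator")
  expect_error(request_control(st4, "guest"), "not a member")
})

test_that("only the holder (or sole member) can mutate trees", {
  p <- create_project("prj", "u1")
  trees <- random_trees(4, 1, seed = 3)
  # sole member may import without the token
  p <- import_trees(p, "Collection 1", trees, "u1")
  p <- add_member(p, "u2", "u1")
  expect_error(import_trees(p, "Collection 1", trees, "u2"),
               "control required")
  p <- project_control(p, "request", "u2")
  p <- import_trees(p, "Collection 1", trees, "u2")
  expect_length(p$collections[[1]]$trees, 2)
  # a detached member is rejected even while holding
  p <- set_sync(p, "u2", FALSE)
  expect_error(import_trees(p, "Collection 1", trees, "u2"), "detached")
  p <- set_sync(p, "u2", TRUE)
  expect_silent(import_trees(p, "Collection 1", trees, "u2"))
})

test_that("check_access follows the privacy policy and is monotone", {
  p <- create_project("prj", "u1")
  p <- add_member(p, "u2", "u1")
  expect_equal(check_access(p, "guest", "read"), "deny")
  expect_equal(check_access(p, "u2", "read"), "allow")
  pub <- set_status(p, "public", "u1")
  expect_equal(check_access(pub, "guest", "read"), "allow")
  expect_equal(check_access(pub, "guest", "write"), "deny")
  expect_equal(check_access(pub, "u2", "write"), "allow")
  # monotone: guest-allowed implies member-allowed; private-read implies
  # public-read
  for (act in c("read", "write")) {
    if (check_access(pub, "guest", act) == "allow")
      expect_equal(check_access(pub, "u2", act), "allow")
    if (check_access(p, "guest", act) == "allow")
      expect_equal(check_access(pub, "guest", act), "allow")
  }
})

test_that("backup and restore snapshot the collections exactly", {
  p <- create_project("prj", "u1")
  p <- import_trees(p, "Collection 1",
                    list(g1 = parse_newick("((A,B),(C,D));")), "u1")
  p <- backup(p, "before")
  snapshot <- p$collections
  p <- restore(p, "before")
  expect_identical(p$collections, snapshot)
  # edit then restore reverts the edit
  p$collections[[1]]$trees$g1 <-
    manual_swap(p$collections[[1]]$trees$g1, "A", "C")
  expect_false(identical(p$collections, snapshot))
  p <- restore(p, "before")
  expect_identical(p$collections, snapshot)
  expect_true("before" %in% names(p$backups))
  expect_error(restore(p, "nope"), "unknown backup label")
  expect_equal(p$timeline$kind[nrow(p$timeline)], "restore")
})

test_that("todo items move to the timeline when done", {
  p <- add_todo(create_project("prj", "u1"), "root the gene trees")
  p <- complete_task(p, "root the gene trees", "u1")
  expect_length(p$todo, 0)
  expect_equal(p$timeline$kind[nrow(p$timeline)], "task_done")
  expect_error(complete_task(p, "nope", "u1"), "no such task")
})

test_that("timeline is append-only and ordered", {
  p <- create_project("prj", "u1")
  for (i in 1:5)
    p <- import_trees(p, "Collection 1", random_trees(4, 1, seed = i), "u1")
  expect_equal(p$timeline$seq, 1:5)
  expect_true(!is.unsorted(p$timeline$timestamp))
})

test_that("projects persist to disk and reload identically", {
  p <- create_project("disk trial", "u1")
  p <- add_member(p, "u2", "u1")
  p <- project_control(p, "request", "u1")
  trees <- list(a = set_color(parse_newick("((A,B),C);"), "A", "blue"),
                b = parse_newick("((C,D),(E,F));"))
  p <- import_trees(p, "Collection 1", trees, "u1")
  p <- rename_collection(p, "Collection 2", "species trees")
  p <- backup(p, "v1")
  p <- project_control(p, "request", "u2")
  p <- project_control(p, "accept", "u1", requester = "u2")
  dir <- withr::local_tempdir()
  save_project(p, dir)
  q <- load_project(dir)
  expect_equal(q$name, p$name)
  expect_equal(q$members, p$members)
  expect_equal(q$control$holder, "u2")
  expect_equal(vapply(q$collections, `[[`, character(1), "name"),
               c("Collection 1", "species trees"))
  expect_identical(lapply(q$collections[[1]]$trees, write_newick),
                   lapply(p$collections[[1]]$trees, write_newick))
  expect_identical(annotations_df(q$collections[[1]]$trees$a),
                   annotations_df(p$collections[[1]]$trees$a))
  expect_equal(names(q$backups), "v1")
  expect_equal(q$timeline$kind, p$timeline$kind)
})

test_that("random event sequences never yield two holders", {
  members <- paste0("u", 1:5)
  set.seed(1234)
  for (run in 1:60) {
    p <- create_project("prj", "u1")
    for (m in members[-1]) p <- add_member(p, m, "u1")
    for (step in 1:40) {
      op <- sample(c("request", "accept", "decline", "take"), 1)
      actor <- sample(members, 1)
      req <- if (length(p$control$pending))
        sample(p$control$pending, 1) else sample(members, 1)
      p <- tryCatch(project_control(p, op, actor, requester = req),
                    error = function(e) p)
      holder <- p$control$holder
      expect_length(holder, 1)
      expect_true(is.na(holder) || holder %in% members)
      expect_false(anyDuplicated(p$control$pending) > 0)
      expect_false(isTRUE(p$control$holder %in% p$control$pending))
    }
  }
})
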