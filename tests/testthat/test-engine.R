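test_that("a first scrape adds every typed entry; a rescrape only updates", {
  repo <- generateRepository(c(2, 1, 1, 2, 1, 1), filesPerArchive = 2,
                             seed = 17)
  n_entries <- sum(repoCounts(repo))
  t1 <- t0() + days(1)
  r1 <- scrape_repo(roadmapGraph(), repo, t1)
  expect_identical(unname(reportCounts(r1$report)[c("added", "updated")]),
                   c(n_entries, 0L))
  expect_identical(sum(reportPerKind(r1$report)), n_entries)
  expect_identical(unname(countByKind(r1$graph)["File"]),
                   unname(repoCounts(repo)["files"]))

  t2 <- t1 + days(1)
  r2 <- scrape_repo(r1$graph, repo, t2)
  expect_identical(unname(reportCounts(r2$report)[c("added", "updated")]),
                   c(0L, n_entries))
  ## UUID set invariant under rescrape
  expect_identical(sort(unname(knownURLs(r2$graph))),
                   sort(unname(knownURLs(r1$graph))))
  recs <- graphRecords(r2$graph)
  expect_true(all(recs$firstSeen == t1))   # write-once
  expect_true(all(recs$lastSeen == t2))    # all advanced
})

test_that("rescraping with the same timestamp is idempotent", {
  repo <- tiny_repo()
  t1 <- t0() + days(1)
  g1 <- scrape_repo(roadmapGraph(), repo, t1)$graph
  g2 <- scrape_repo(g1, repo, t1)$graph
  expect_identical(serializeGraph(g1, "ntriples"),
                   serializeGraph(g2, "ntriples"))
})

test_that("files under extra-deep directories link to the depth-6 archive", {
  repo <- tiny_repo()
  nd <- repoNodes(repo)
  archive <- nd$path[nd$isDirectory & lengths(strsplit(nd$path, "/")) == 6]
  repo <- evolveRepository(repo, list(
    list(advance = 60),
    list(add = paste0(archive, "/nested/deeper/extra.txt"))))
  g <- scrape_repo(roadmapGraph(), repo, t0() + days(1))$graph
  recs <- graphRecords(g, "File")
  deep <- recs[grepl("extra.txt", recs$url), ]
  expect_identical(nrow(deep), 1L)
  rec <- recordsFromGraph(g, deep$uuid)[[1]]
  ## linked ancestors stop at the archive; untyped containers get no record
  expect_identical(names(recordLinks(rec)), resourceKinds()[1:6])
  expect_identical(unname(recordLinks(rec)["Archive"]),
                   mintUUID(fixture_url(archive, TRUE)))
  expect_false(any(grepl("nested", graphRecords(g)$label)))
})

test_that("removed files keep their stale last-seen date and are detected", {
  repo <- generateRepository(c(1, 1, 1, 2, 1, 1), filesPerArchive = 3,
                             seed = 23)
  t1 <- t0() + days(1)
  g <- scrape_repo(roadmapGraph(), repo, t1)$graph
  expect_identical(nrow(detectRemoved(g)), 0L)   # single scrape: nothing lags

  victims <- repo_files(repo)[1:3]
  repo2 <- evolveRepository(repo, c(list(list(advance = 3600)),
                                    lapply(victims, function(p) list(remove = p))))
  t2 <- t1 + days(1)
  g2 <- scrape_repo(g, repo2, t2)$graph
  rem <- detectRemoved(g2)
  expect_identical(plain_urls(rem$url), plain_urls(fixture_url(victims)))
  expect_true(all(rem$lastSeen == t1))
  kept <- graphRecords(g2)
  expect_true(all(kept$lastSeen[!kept$url %in% rem$url] == t2))
})

test_that("removing a folder reports the folder and all its descendants", {
  repo <- generateRepository(c(2, 1, 1, 1, 1, 1), filesPerArchive = 2,
                             seed = 29)
  t1 <- t0() + days(1)
  g <- scrape_repo(roadmapGraph(), repo, t1)$graph
  nd <- repoNodes(repo)
  doomed_dir <- nd$path[nd$isDirectory & lengths(strsplit(nd$path, "/")) == 4][1]
  doomed <- nd$path[nd$path == doomed_dir |
                    startsWith(nd$path, paste0(doomed_dir, "/"))]
  repo2 <- evolveRepository(repo, list(list(advance = 3600),
                                       list(remove = doomed_dir)))
  g2 <- scrape_repo(g, repo2, t1 + days(1))$graph
  rem <- detectRemoved(g2)
  expect_identical(plain_urls(rem$url), plain_urls(fixture_url(doomed)))
})

test_that("as-of resolution follows the add/remove timeline", {
  repo <- tiny_repo(seed = 37)
  nd <- repoNodes(repo)
  archive <- nd$path[nd$isDirectory & lengths(strsplit(nd$path, "/")) == 6]
  early_file <- repo_files(repo)[1]

  t1 <- t0() + days(1)
  g <- scrape_repo(roadmapGraph(), repo, t1)$graph
  ## file added between t1 and t2; early file removed after t1
  repo <- evolveRepository(repo, list(
    list(advance = 3600), list(add = paste0(archive, "/late_arrival.txt")),
    list(remove = early_file)))
  t2 <- t1 + days(1)
  g <- scrape_repo(g, repo, t2)$graph
  t3 <- t2 + days(1)
  g <- scrape_repo(g, repo, t3)$graph

  expect_identical(nrow(resolveAsOf(g, t0() - days(1))), 0L)
  url_late <- fixture_url(paste0(archive, "/late_arrival.txt"))
  expect_false(url_late %in% resolveAsOf(g, t1)$url)
  expect_true(url_late %in% resolveAsOf(g, t2)$url)
  expect_true(url_late %in% resolveAsOf(g, t3)$url)
  ## present at t1 only: excluded from t2 onwards
  url_early <- fixture_url(early_file)
  expect_true(url_early %in% resolveAsOf(g, t1)$url)
  expect_false(url_early %in% resolveAsOf(g, t2)$url)
})

test_that("last-modified mode reconstructs pre-scrape repository states", {
  repo <- tiny_repo(seed = 43)
  archive <- with(repoNodes(repo),
                  path[isDirectory & lengths(strsplit(path, "/")) == 6])
  ## one file modified upstream long after the others
  repo <- evolveRepository(repo, list(
    list(advance = days(30)), list(add = paste0(archive, "/recent.txt"))))
  g <- scrape_repo(roadmapGraph(), repo, t0() + days(60))$graph
  old <- resolveAsOf(g, t0() + days(1), mode = "last_modified")
  expect_false(any(grepl("recent.txt", old$url)))
  expect_identical(nrow(old), length(repo_files(tiny_repo(seed = 43))))
  all_now <- resolveAsOf(g, t0() + days(31), mode = "last_modified")
  expect_true(any(grepl("recent.txt", all_now$url)))
})

test_that("random evolution scenarios replay exactly at every scrape point", {
  for (seed in c(101, 202, 303)) {
    sc <- run_scenario(seed, n_scrapes = 4)
    for (t_s in sc$times) {
      got <- plain_urls(resolveAsOf(sc$graph, t_s)$url)
      want <- plain_urls(oracle_urls_at(sc$repo, t_s))
      expect_identical(got, want, info = paste("seed", seed))
    }
    ## removed + current partition everything ever seen
    rem <- detectRemoved(sc$graph)
    recs <- graphRecords(sc$graph)
    cur <- recs[recs$lastSeen == max(recs$lastSeen), ]
    expect_identical(sort(c(rem$uuid, cur$uuid)), sort(recs$uuid))
    expect_length(intersect(rem$uuid, cur$uuid), 0)
  }
})

test_that("provenance dates are monotone across a scrape sequence", {
  sc <- run_scenario(404, n_scrapes = 4)
  ## rebuild stepwise to watch the dates
  repo <- sc$repo
  g <- roadmapGraph()
  first_seen <- list()
  last_seen <- list()
  for (t_s in sc$times) {
    g <- scrape_repo(g, repo, t_s)$graph   # final tree rescraped: fine for
    recs <- graphRecords(g)                # monotonicity of the dates
    for (i in seq_len(nrow(recs))) {
      u <- recs$uuid[i]
      if (!is.null(first_seen[[u]]))
        expect_identical(recs$firstSeen[i], first_seen[[u]])
      first_seen[[u]] <- recs$firstSeen[i]
      if (!is.null(last_seen[[u]]))
        expect_true(recs$lastSeen[i] >= last_seen[[u]])
      last_seen[[u]] <- recs$lastSeen[i]
    }
  }
})

test_that("detecting removals on an empty graph is an error", {
  expect_error(detectRemoved(roadmapGraph()), "empty graph")
})
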