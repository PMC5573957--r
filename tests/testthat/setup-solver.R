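# shut the persistent MILP worker down once the whole suite has run
withr::defer(resinopt::solver_stop(), teardown_env())
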