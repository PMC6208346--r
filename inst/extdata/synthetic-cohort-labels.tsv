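sample-0001	early
sample-0002	early
sample-0003	early
sample-0004	early
sample-0005	early
sample-0006	early
sample-0007	early
sample-0008	early
sample-0009	early
sample-0010	early
sample-0011	early
sample-0012	early
sample-0013	advanced
sample-0014	advanced
sample-0015	advanced
sample-0016	advanced
sample-0017	advanced
sample-0018	advanced
sample-0019	advanced
sample-0020	advanced
sample-0021	advanced
sample-0022	advanced
sample-0023	advanced
sample-0024	advanced
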