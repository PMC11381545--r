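species_id	gene_id
sp_0001	sp_0001_g001
sp_0001	sp_0001_g002
sp_0001	sp_0001_g003
sp_0001	sp_0001_g004
sp_0001	sp_0001_g005
sp_0002	sp_0002_g001
sp_0002	sp_0002_g002
sp_0002	sp_0002_g003
sp_0002	sp_0002_g004
sp_0002	sp_0002_g005
sp_0003	sp_0003_g001
sp_0003	sp_0003_g002
sp_0003	sp_0003_g003
sp_0003	sp_0003_g004
sp_0003	sp_0003_g005
sp_0004	sp_0004_g001
sp_0004	sp_0004_g002
sp_0004	sp_0004_g003
sp_0004	sp_0004_g004
sp_0004	sp_0004_g005
sp_0005	sp_0005_g001
sp_0005	sp_0005_g002
sp_0005	sp_0005_g003
sp_0005	sp_0005_g004
sp_0005	sp_0005_g005
sp_0006	sp_0006_g001
sp_0006	sp_0006_g002
sp_0006	sp_0006_g003
sp_0006	sp_0006_g004
sp_0006	sp_0006_g005
sp_0007	sp_0007_g001
sp_0007	sp_0007_g002
sp_0007	sp_0007_g003
sp_0007	sp_0007_g004
sp_0007	sp_0007_g005
sp_0008	sp_0008_g001
sp_0008	sp_0008_g002
sp_0008	sp_0008_g003
sp_0008	sp_0008_g004
sp_0008	sp_0008_g005
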