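# depth_mm=132
# site_diameter_um=0.56399999999999995
y_keV_um,d_y
148,2.0209084334147571e-14
148.05000000000001,9.8114211427891941e-14
148.09999999999999,4.5766259607197522e-13
148.15000000000001,2.0511014547190154e-12
148.19999999999999,8.8319598525456812e-12
148.25,3.6538881633458375e-11
148.30000000000001,1.4523846007171653e-10
148.34999999999999,5.546719976660422e-10
148.40000000000001,2.03525611265832e-09
148.44999999999999,7.1751356318543126e-09
148.5,2.4303531399293144e-08
148.55000000000001,7.9092785624999585e-08
148.59999999999999,2.4730482000660232e-07
148.65000000000001,7.4294473782220841e-07
148.69999999999999,2.1444141378785414e-06
148.75,5.9468780589371907e-06
148.80000000000001,1.5845196364131764e-05
148.84999999999999,4.0563408261942717e-05
148.90000000000001,9.9769885160224238e-05
148.94999999999999,0.00023577227102611459
149,0.00053532090305954147
149.05000000000001,0.0011677877031660423
149.09999999999999,0.0024476077204548877
149.15000000000001,0.0049288766738924562
149.19999999999999,0.0095363528058579807
149.25,0.01772739364775203
149.30000000000001,0.031661806331923892
149.34999999999999,0.054331876934739266
149.40000000000001,0.089578121179376496
149.44999999999999,0.1418983713849116
149.5,0.21596386605275225
149.55000000000001,0.31580063320360247
149.59999999999999,0.44368333871780608
149.65000000000001,0.59890986254299849
149.69999999999999,0.7767442199328094
149.75,0.96788289807657346
149.80000000000001,1.1587662110459731
149.84999999999999,1.3328984115671803
149.90000000000001,1.4730805612133067
149.94999999999999,1.5641707759018093
150,1.5957691216057308
150.05000000000001,1.5641707759018093
150.09999999999999,1.4730805612133067
150.15000000000001,1.3328984115671803
150.19999999999999,1.1587662110459731
150.25,0.96788289807657346
150.30000000000001,0.7767442199328094
150.34999999999999,0.59890986254299849
150.40000000000001,0.44368333871780608
150.44999999999999,0.31580063320360247
150.5,0.21596386605275225
150.55000000000001,0.1418983713849116
150.59999999999999,0.089578121179376496
150.65000000000001,0.054331876934739266
150.69999999999999,0.031661806331923892
150.75,0.01772739364775203
150.80000000000001,0.0095363528058579807
150.84999999999999,0.0049288766738924562
150.90000000000001,0.0024476077204548877
150.94999999999999,0.0011677877031660423
151,0.00053532090305954147
151.05000000000001,0.00023577227102611459
151.09999999999999,9.9769885160224238e-05
151.15000000000001,4.0563408261942717e-05
151.19999999999999,1.5845196364131764e-05
151.25,5.9468780589371907e-06
151.30000000000001,2.1444141378785414e-06
151.34999999999999,7.4294473782220841e-07
151.40000000000001,2.4730482000660232e-07
151.44999999999999,7.9092785624999585e-08
151.5,2.4303531399293144e-08
151.55000000000001,7.1751356318543126e-09
151.59999999999999,2.03525611265832e-09
151.65000000000001,5.546719976660422e-10
151.69999999999999,1.4523846007171653e-10
151.75,3.6538881633458375e-11
151.80000000000001,8.8319598525456812e-12
151.84999999999999,2.0511014547190154e-12
151.90000000000001,4.5766259607197522e-13
151.94999999999999,9.8114211427891941e-14
152,2.0209084334147571e-14
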