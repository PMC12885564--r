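model_id,feature,importance,metric,performance
logistic,tenure,1.42,abs_coefficient,0.79
logistic,num_products,0.88,abs_coefficient,0.79
logistic,credit_score,0.61,abs_coefficient,0.79
logistic,balance,0.37,abs_coefficient,0.79
logistic,age,0.22,abs_coefficient,0.79
logistic,online_usage,0.05,abs_coefficient,0.79
tree,tenure,41.2,impurity,0.77
tree,credit_score,18.9,impurity,0.77
tree,num_products,15.3,impurity,0.77
tree,online_usage,8.1,impurity,0.77
tree,balance,5.6,impurity,0.77
tree,age,2.4,impurity,0.77
xgb,age,0.31,gain,0.84
xgb,tenure,0.27,gain,0.84
xgb,balance,0.18,gain,0.84
xgb,num_products,0.13,gain,0.84
xgb,credit_score,0.08,gain,0.84
xgb,online_usage,0.03,gain,0.84
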